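---
title: "Deriving and validating harmonic cross-link parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating harmonic cross-link parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkforge)
```

## The problem

Covalent cross-links between lysine and arginine side chains — the
sugar-derived imidazolium adducts of the DOGDIC/GODIC/MODIC family that
accumulate in aging collagen — are absent from standard protein force
fields. Simulating a cross-linked protein therefore requires (i) harmonic
bond and angle parameters for the new covalent unit, derived from a
quantum-mechanical (QM) Hessian of the optimized cross-link, (ii) a
topology that splits the cross-link into two residue templates joined by
special inter-residue bond records so that each half can live on its own
peptide chain, and (iii) validation that the derived classical model
reproduces the QM vibrational structure. Once simulations exist, the
structural consequences are quantified with hydrogen-bond counts, solvent
accessible surface area (SASA), RMSD-based conformational analysis, PCA,
and centroid extraction. `xlinkforge` implements this whole chain on
testable foundations.

## Force-constant derivation

The QM Hessian $H$ is the $3N \times 3N$ matrix of second derivatives of
the electronic energy with respect to Cartesian displacements, read from a
formatted-checkpoint dialect (lower-triangular storage, Hartree/Bohr²) and
converted once to the internal unit system: nm, kJ/mol, amu, with 1 Hartree
= 2625.4996 kJ/mol and 1 Bohr = 0.0529177 nm. All emitted constants use the
half-k harmonic convention $V = \tfrac12 k (x - x_0)^2$ — the classic
interoperability trap, so it is stated here once and used everywhere.

**Bonds.** For a bonded pair $(a,b)$ the interatomic block
$B = -\partial^2 E/\partial r_a \partial r_b$ is diagonalized and the
eigenvalues are projected on the unit bond vector $\hat u$
(the Seminario projection):
$$k_b = \tfrac12\left[\sum_m \lambda_m |\hat u \cdot v_m|\Big|_{B} +
        \sum_m \lambda_m |\hat u \cdot v_m|\Big|_{B^\top}\right],$$
with the equilibrium length read from the optimized geometry. For an
isolated harmonic bond this is exact; for bonds embedded in a molecule the
angle terms leak into the block at order $k_\theta / (R^2 k_b)$, which for
physically realistic stiffnesses (bond constants of a few $10^5$
kJ mol⁻¹ nm⁻², angle constants of a few $10^2$ kJ mol⁻¹ rad⁻²) is a
few percent.

**Angles.** Two realizations are provided. The default (`"arm_block"`)
reads the bending stiffness from the 1–3 block between the two arm atoms
$i$ and $k$:
$$k_\theta = R_{ij} R_{kj}\,\bigl|\hat u_{Pi}^\top\, H_{ik}\, \hat
u_{Pk}\bigr|,$$
where $\hat u_{Pi}$, $\hat u_{Pk}$ are the in-plane unit vectors
perpendicular to the two arms. Because bond-stretch terms never contribute
to the 1–3 interatomic block of a bond+angle harmonic energy, this
projection recovers a generating angle constant *exactly* on analytic
fixtures — which is what makes the derivation stage testable end to end.
The classical two-arm reciprocal form
$1/k_\theta = 1/(R_{ij}^2 S_i) + 1/(R_{kj}^2 S_k)$ is retained as
`method = "seminario_reciprocal"`; on an idealized single-angle Hessian it
systematically underestimates (the series combination halves a lone angle
spring — the package's tests demonstrate this directly), so it is not the
default. This is a deliberate design deviation, made when implementation
showed the reciprocal form cannot meet the package's own recovery targets
on analytic oracles.

**What recovery tests establish.** On synthetic molecules built by
`make_toy_molecule()` — whose Hessian *is* the analytic second derivative
of the generating force field — bonds recover exactly when isolated, to
within 4% in the five-atom coupled chain, and angles and equilibrium
values recover to machine precision. These statements are verified by the
test suite, not assumed. They do not establish agreement with any specific
third-party implementation's numbers, which depend on unpublished
block-averaging conventions.

## Topology construction

`split_crosslink()` removes the declared boundary bonds from the molecular
bond graph (inferred from covalent radii × 1.2, or supplied explicitly)
and requires exactly two remaining components; capping methyl groups —
identified by an explicit cap list, never by pattern detection — are
excluded from both halves. Each boundary bond becomes a special-bond record
carrying its equilibrium length from the geometry. The zero-net-charge
invariant ($|\sum q| \le 10^{-6}$ e over the two halves, caps excluded, as
in restrained charge fitting against neutral capped groups) is checked but
never silently repaired. Writers for residue templates, special bonds, and
bonded parameter tables emit fixed-format, deterministically ordered text
and round-trip through their paired readers.

## Normal-mode validation

`build_mm_hessian()` assembles the analytic Hessian of
$\sum \tfrac12 k_b (b-b_0)^2 + \sum \tfrac12 k_\theta (\theta-\theta_0)^2$
including the geometry-dependent terms away from equilibrium, and is
checked elementwise against a central-finite-difference oracle.
`mode_spectrum()` diagonalizes the mass-weighted matrix
$F_{ij} = H_{ij}/\sqrt{m_i m_j}$ and reports signed wavenumbers
$\tilde\nu = \mathrm{sign}(\lambda)\sqrt{|\lambda|}/(2\pi c)$; imaginary
modes come out negative, mirroring the imaginary-frequency check applied
to QM optimizations. Rigid translations/rotations are not projected out;
modes below 5 cm⁻¹ (configurable) are counted as near-zero after the fact,
because "six very small leading wavenumbers" is itself the validation
statement for a nonlinear equilibrium structure.

Two physical caveats the test suite encodes explicitly: a molecule whose
force field leaves torsions unconstrained has extra floppy zero modes
(the five-atom chain has 6 + 2), and a *linear* molecule cannot carry a
$\tfrac12 k(\theta - \pi)^2$ term (the angle is non-smooth at 180°), so
the linear five-zero-mode case is built with an analytic transverse-bend
Hessian instead.

`compare_spectra()` aligns MM to QM modes by ascending rank after dropping
near-zero modes — rank alignment, not eigenvector matching, because that
is how such comparisons are plotted — and reports per-mode differences and
the RMS over the requested leading modes.

## Trajectory analyses

*Hydrogen bonds.* A triple (donor heavy atom, bonded hydrogen, acceptor)
counts when the donor–acceptor distance is ≤ 0.3 nm and the D–H–A angle is
≥ 120°. The 3 Å criterion is read as the donor–acceptor heavy-atom
distance (the common convention of trajectory tooling); a
hydrogen–acceptor mode is one flag away. Periodic systems use
minimum-image displacements under the full triclinic cell. Detection is
property-tested against a brute-force triple loop on seeded random frames,
and per-frame counts, per-donor tallies, and per-acceptor tallies are
required to sum identically.

*SASA.* Shrake–Rupley quadrature with a deterministic golden-spiral
lattice, 960 points per atom, probe radius 0.14 nm (the canonical water
probe) over per-element Bondi radii; passing `radii =` a single value
reproduces the literal uniform-radius reading. The isolated-sphere
quadrature error is bounded at 0.5% by test.

*RMSD, net-RMSD, PCA, centroid.* Superposition is Kabsch SVD with the
determinant correction (proper rotations only). The net-RMSD matrix is the
full all-pairs backbone RMSD ("against every previous frame", mirrored).
PCA superposes twice (to frame 1, then to the mean structure), then
eigendecomposes the 3M×3M positional covariance; variance conservation to
1e-8 relative is an invariant, not a hope. The centroid frame maximizes
$\sum_j s_{ij}$ with $s_{ij} = \exp(-\beta\, d_{ij}/\bar d)$, $\beta = 1$
by default; the distance-to-similarity transform is not specified by the
methodology this package follows, so the scale-free exponential with a
config-exposed sharpness was chosen once. Ties break to the lowest frame
index; identical frames return frame 1.

*Statistics.* Shapiro–Wilk and Fligner–Killeen wrap the reference
implementations in base R's stats package; the comparison report applies
the normality-gated rule (Fligner–Killeen when either sample rejects
normality at $\alpha = 0.001$, an F test otherwise). Backbone heavy atoms
are N, CA, C, O; the equilibration discard is a frame fraction, default
0.25 (the 50-of-200 ns convention).

## The synthetic world

`make_toy_molecule()` builds molecules whose Hessian is the analytic
ground truth of the generating force field. Generating constants sit at
realistic magnitudes (stretches of 2.5–4.6 × 10⁵ kJ mol⁻¹ nm⁻², bends of
3–7 × 10² kJ mol⁻¹ rad⁻²); with bonds much softer than that, the angle
leakage into interatomic blocks dominates and no block-projection scheme
recovers them — the generator states a realistic world rather than an
adversarial one, and this choice was made once, on physical grounds.

`make_crosslink_fixture()` produces reduced cross-link-shaped molecules
carrying the atom-naming conventions of the default donor/acceptor sets
(HN/HD5/HD6/HD10/HD12/HD13; N/ND2/ND4–ND6/OD1–OD5), an explicit bond
graph, a declared boundary, caps, and zero-sum charges over the central
fragment. The three kinds differ in oxygen decoration, loosely mirroring
the 3-deoxyglucosone-, glyoxal-, and methylglyoxal-derived chemistry; they
are *synthetic stand-ins*, not the real molecules.

`make_synthetic_trajectory()` produces three helical chains (A/B/C) with
N/CA/C/O backbone naming plus a bank of donor/acceptor probe groups.
Planted hydrogen bonds are enforced *post-noise* by projecting the
hydrogen and acceptor onto the target geometry, so criteria satisfaction
is exact when demanded; per-frame planted counts may follow a Binomial
model, and the generating truth is always returned beside the data — no
test reads truth out of the data itself. Frames may alternate between two
backbone conformers to create a two-block net-RMSD structure. What this
world does **not** emulate: explicit solvent, realistic helical
geometry/fraying, correlated dynamics, or the real collagen unit cell.
A green test therefore establishes algorithmic correctness against stated
geometry, never biophysical realism, and the headline solvated-fibril
statistics (median bond counts, SASA shifts) are out of reach at desk
scale by design.

## Numerical choices and limitations

- Collinearity guard 1e-4 rad, coincidence guard 1e-6 nm
  (config-overridable defaults); near-zero mode threshold 5 cm⁻¹.
- Interatomic blocks of analytic bond+angle Hessians can be mildly
  non-symmetric; eigenvalues are taken real with a warning if the
  imaginary part exceeds 5% — real QM blocks sit far below this.
- No Urey–Bradley (1-3) terms, no dihedral/improper derivation, no
  Lennard-Jones or charge fitting: dihedrals were assigned from existing
  force-field analogy in the workflow this package supports, a heuristic
  that is not reproducible from published information and is out of scope.
- The MM normal-mode Hessian is bonded-only; an engine-side analysis would
  include nonbonded terms, so the comparison validates the logic of the
  spectrum check, not any particular published curve.
- Binary trajectory formats (XTC/DCD) are not read; multi-MODEL PDB and
  GRO text trajectories are.
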