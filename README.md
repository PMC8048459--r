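# xlinkforge

Harmonic force-field parameterization and trajectory analysis for covalent
protein cross-links, in R.

Sugar-derived lysine–arginine cross-links (the DOGDIC/GODIC/MODIC
imidazolium family of advanced glycation end-products) are not covered by
standard protein force fields. To simulate a cross-linked protein you must
derive harmonic bonded parameters for the new covalent unit from a
quantum-mechanical Hessian, split the cross-link into two residue
templates joined by special inter-residue bond records, validate the
classical model against the QM vibrational spectrum, and then analyze the
resulting trajectories. `xlinkforge` implements that pipeline for
structural bioinformaticians and simulators:

- **qm I/O** — formatted-checkpoint parsing (lower-triangular Cartesian
  force constants, Hartree/Bohr²), unit normalization (nm, kJ/mol, amu),
  bond-pair / angle-triplet request files.
- **bonded parameters** — Seminario interatomic-block eigen-projection for
  bonds, `k_b = Σ_m λ_m |û·v_m|` over the 3×3 block `−∂²E/∂r_a∂r_b`, and
  an exact arm–arm block projection for angles,
  `k_θ = R_ij R_kj |û_Pi·H_ik·û_Pk|`, in the `V = ½k(x−x₀)²` convention.
- **topology emission** — two-residue split with cap exclusion, zero-net
  charge checking (|Σq| ≤ 1e-6 e), deterministic residue-template /
  special-bond / bonded-parameter writers that round-trip.
- **normal modes** — analytic MM Hessian, mass-weighted spectrum
  `ν̃ = sign(λ)√|λ|/(2πc)`, zero-mode counting, rank-aligned comparison
  against QM wavenumbers.
- **trajectory analysis** — geometric hydrogen bonds (0.3 nm / 120°,
  minimum-image, triclinic), Shrake–Rupley SASA (960 golden-spiral points,
  0.14 nm probe), Kabsch RMSD, all-pairs net-RMSD, backbone PCA, centroid
  extraction via `s_ij = exp(−β d_ij/d̄)`, Shapiro–Wilk and
  Fligner–Killeen tests.
- **synthetic data** — toy molecules whose Hessians are analytic ground
  truth, cross-link-shaped fixtures with known partitions, and
  triple-helix-like trajectories with planted hydrogen-bond geometry, so
  every stage is testable without external data.

## Worked example

Derive parameters for a water-like toy molecule from its analytic Hessian
and validate them by normal-mode analysis:

```r
library(xlinkforge)

toy <- make_toy_molecule(recipe_water_like())
ps <- derive_all(toy$hessian, toy$geometry,
                 pairs = list(c(1, 2), c(1, 3)),
                 triplets = list(c(2, 1, 3)))
ps$bonds
#>   i j name_i name_j    k_b    b0
#> 1 1 2     O1     H2 463726 0.096
#> 2 1 3     O1     H3 463726 0.096
ps$angles
#>   i j k name_i name_j name_k k_theta theta0
#> 1 2 1 3     H2     O1     H3     317  104.5
```

The generating constants were k_b = 462750 kJ mol⁻¹ nm⁻² (recovered to
0.2%; the small excess is angle–bond coupling in the interatomic blocks)
and k_θ = 317 kJ mol⁻¹ rad⁻² with θ₀ = 104.5° (recovered exactly). The
rebuilt spectrum shows the six near-zero rigid-body modes followed by the
three vibrations:

```r
sp <- mode_spectrum(toy$geometry,
                    build_mm_hessian(toy$geometry, as_harmonic_ff(ps)))
round(sp$wavenumbers, 1)
#> [1]    0.0    0.0    0.0    0.0    0.0    0.0 1437.7 3686.0 3740.0
```

(bend, symmetric and antisymmetric stretch, in cm⁻¹ — water-like, as the
constants intended). Hydrogen-bond counting on a synthetic trajectory with
Binomial(12, 0.6) planted bonds per frame recovers the generating model:

```r
st <- make_synthetic_trajectory(n_frames = 50,
                                planted = list(n = 12, p = 0.6), seed = 7)
hb <- hbond_distribution(st$traj, st$bonds, hbond_criteria(),
                         st$donor_sel, st$acceptor_sel)
hb$summary
#>  median     min     max    mean      sd
#>    7.00    3.00   11.00    6.96    2.01
```

(the generating mean is 12 × 0.6 = 7.2).

## Command line

A CLI mirroring the pipeline stages ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/xlinkforge.R", package="xlinkforge"))')" \
  ingest --fchk mol.fchk --pairs pairs.txt --triplets triplets.txt --out parsed.json
# then: derive, nma, analyze, simulate-fixtures
```

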