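Package: xlinkforge
Title: Harmonic Force-Field Parameterization and Trajectory Analysis for
    Protein Cross-Links
Version: 0.1.0
Authors@R:
    person("Maintainer", "xlinkforge", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to derive harmonic bonded force constants (bond lengths
    and bond angles) from a quantum-mechanical Cartesian Hessian via the
    Seminario interatomic-block projection, to build and write two-residue
    cross-link topologies with zero-net-charge bookkeeping in GROMACS-style
    dialects (residue templates, special bonds, bonded parameter tables),
    to validate the derived parameters by mass-weighted normal-mode
    analysis against reference vibrational wavenumbers, and to analyze
    protein trajectories: geometric hydrogen-bond detection, Shrake-Rupley
    solvent accessible surface area, Kabsch RMSD and all-pairs net-RMSD
    matrices, backbone principal component analysis, centroid-structure
    extraction, and the accompanying distribution tests. A synthetic-data
    module generates toy molecules with analytic Hessians and multi-chain
    helical trajectories with planted hydrogen-bond geometry so that every
    stage is testable against analytic oracles without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
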