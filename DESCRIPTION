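Package: selectiscreen
Title: Dual-Target Selectivity Virtual Screening with a
    Desolvation-Corrected Empirical Scoring Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an empirical protein-ligand binding free energy
    function combining 12-6 van der Waals, angle-weighted 12-10 hydrogen
    bond, sigmoidally screened electrostatic, and torsional entropy terms
    with a solvent-contact ligand dehydration penalty based on Gaussian
    atomic occupancies.  Provides precomputed affinity grid maps with
    trilinear interpolation, a seeded stochastic pose optimizer, a
    two-track selectivity screening pipeline for scoring candidate
    inhibitors against a mutant and a wild-type receptor simultaneously
    (including hinge hydrogen-bond filtering, Lipinski profiling and
    Tanimoto leader clustering), structure-based enumeration of
    substituted derivatives for de novo design, and deterministic
    synthetic fixture generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
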