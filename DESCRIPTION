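Package: myolv
Title: Cross-Bridge Distribution Kinetics Coupled to Left-Ventricular
    Finite-Element Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates cardiac contraction from the half-sarcomere to the
    organ. A two-state cross-bridge distribution engine with calcium
    activation, cooperativity and interfilamentary movement supplies the
    active stress law; the passive myocardium follows the Guccione
    transversely isotropic hyperelastic law. Includes single-element
    cellular protocols (maximal tension, force-pCa with Hill fits,
    tension redevelopment, twitch), an idealized truncated-ellipsoid
    left-ventricle mesh generator, a quasi-static finite-element solver
    driven by a prescribed volumetric flowrate, end-systolic strain and
    torsion post-processing, and a hybrid simulated-annealing plus
    sequential-response-surface parameter estimator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    lhs,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
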