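Package: axonrve
Title: Undulated-Axon Representative Volume Elements for White-Matter
    Micromechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds randomized pseudo-3D representative volume elements
    (RVEs) of undulated axons embedded in extracellular matrix, applies a
    transitional kinematic model of stretch-dependent axon-matrix coupling,
    solves staged uniaxial tension with a total-Lagrangian hyperelastic
    finite element model (one-term Ogden matrix, embedded nonlinear truss
    fibers tied by penalty springs), and identifies the axon shear modulus
    from a target stress-stretch curve by golden-section minimization of the
    squared curve error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
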