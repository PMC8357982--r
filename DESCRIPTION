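Package: sprphase
Title: Single-Shot Phase Retrieval and Refractive-Index Sensing for
    Surface Plasmon Resonance Back-Focal-Plane Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates surface-plasmon-resonance (SPR) back-focal-plane
    (BFP) images of multilayer gold sensors with transfer-matrix Fresnel
    optics, trains a context aggregation network to regress the pupil
    phase from a single amplitude image, and benchmarks the refractive-
    index detection limit of the learned phase readout against classical
    plasmonic-dip estimators (3rd-degree polynomial dip fitting and
    azimuthal angle averaging) under a Poisson shot-noise camera model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
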