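Package: linacqa
Title: Simulation-Based Accuracy Evaluation of Geometric Tests for Linac C-Arms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the statistical accuracy of geometric
    quality-assurance tests of a radiotherapy linear accelerator C-arm.
    Simulates electronic portal imaging device (EPID) exposures of a
    two-module fiducial-ball phantom under nominal machine geometry with
    Gaussian localization noise, reconstructs the machine geometry
    (radiation isocenter, collimator and gantry rotation axes, gantry
    angle, source-to-axis and source-to-detector distances, and the
    radiation-field outline in the isocentric plane) from the noisy
    projections alone, and runs Monte Carlo experiments that characterize
    the dispersion of every reconstructed quantity as a function of the
    test-plan design, the phantom design, and the noise level. Includes
    empirical tail-probability and tolerance-threshold machinery for
    setting probabilistic action thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
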