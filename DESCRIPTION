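Package: synstorm
Title: Two-Color dSTORM Pipeline for Transsynaptic Protein Distance Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-molecule localization microscopy (dSTORM) analysis of the
    nanoscale separation of synaptic protein populations. Provides a synthetic
    two-color movie and localization-table generator with known ground truth
    (blinking emitters, EMCCD Poisson noise, drift, fiducial beads), running
    temporal median background subtraction, threshold-based spot detection
    with center-of-mass sub-pixel localization and intensity/width/asymmetry
    quality filtering, bead-based two-channel registration, redundant
    cross-correlation (RCC) drift correction, super-resolution image
    reconstruction on a 10 nm raster, and the transsynaptic center-of-mass
    distance statistics: 1D line-profile and 2D rectangle COM distances,
    10 nm histograms, and the top-fraction (default 40 percent) mean distance
    estimator that corrects the 2D projection bias of randomly oriented
    synapses, together with its closed-form analytic oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
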