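Package: needletrack
Title: Needle-Guide Tracking in Accelerated Dynamic MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for instrument tracking in
    accelerated dynamic MRI of MR-guided prostate biopsy. Generates synthetic
    dynamic multi-coil k-space phantoms with a moving needle guide, performs
    Cartesian centre-line (ACS) undersampling and zero-filled reconstruction,
    trains a temporally recurrent convolutional reconstruction network with a
    structural-similarity loss and hard data consistency, segments the needle
    guide with a small 2D U-Net, localizes the guide tip by principal-axis
    analysis of segmentation masks, and summarizes tracking feasibility with
    per-sample success rates, Wilson score intervals, t-based inference and
    moment-matched gamma fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
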