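Package: nanomorph
Title: Morphometry and Size-Distribution Analysis of Bioproduced
    Nanoparticles in Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital image-analysis pipeline for quantifying metal
    nanoparticles formed inside microbial cells and imaged by
    transmission electron microscopy. Provides percentile threshold
    segmentation with size-range and edge filtering, per-particle
    morphometry (area, equivalent circular diameter, maximum Feret
    diameter, moment-based ellipse fit, Feret/major-axis and reciprocal
    aspect ratios), particle-size-distribution and roundness-class
    summaries, cell-volume-normalized particle accounting, local
    region-of-interest analysis, and a synthetic micrograph generator
    with exact per-particle ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    grDevices,
    withr,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
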