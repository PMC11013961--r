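Package: tasselcount
Title: Color-Index Filtering and Counting-by-Regression for Maize Tassels
    in UAV Plot Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for isolating and counting maize tassels in plot-level
    aerial (UAV) RGB imagery. Implements a two-step color-index filter
    (Excess Green thresholding to remove soil and shadow, followed by a
    yellow-sensitive tassel index to remove foliage), pixel-sampling
    elimination-rate curves for threshold selection, a counting-by-
    regression engine that trains a small convolutional network on
    Gaussian density-map targets over overlapping 32x32 sub-images and
    predicts per-image counts by sliding-window redistribution, and
    count-accuracy evaluation (MAE, normalized mean square prediction
    error, predictive deviance, Spearman correlation, r-squared threshold
    sweeps, bootstrap uncertainty intervals). A seeded synthetic plot-
    scene generator provides ground-truth test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    Rcpp,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
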