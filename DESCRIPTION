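Package: plumfw
Title: Non-Destructive Plum Fruit Weight Estimation from Image-Derived Dimensions
Version: 0.1.0
Authors@R:
    person("plumfw", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for estimating
    plum (Prunus spp.) fresh fruit weight from top-view images. Provides a
    ground-truthed fruit image and tabular cohort simulator, colour-agnostic
    fruit segmentation by 2-cluster K-means on the CIELAB chromatic channels
    with morphological cleanup, pixel-to-millimetre calibration against a
    10 mm reference square, moment-based extraction of fruit length and
    equatorial diameter, and a suite of weight estimators: five allometric
    forms, multiple linear regression, epsilon-SVR with RBF, Pearson-VII
    (PUK) and degree-2 polynomial kernels, a one-hidden-layer perceptron,
    and an M5-style model tree. Evaluation utilities implement RMSE, the
    coefficient of determination, 70/30 splits, 10-fold cross-validation,
    identity-line diagnostics and cross-cohort transfer validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    jsonlite,
    withr,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
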