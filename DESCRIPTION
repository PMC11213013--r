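Package: abrkit
Title: Automated Analysis of Auditory Brainstem Response Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Batch analysis of auditory brainstem response (ABR) recordings:
    Wave 1-5 peak and trough detection with a convolutional-network latency
    regressor followed by constrained local-extremum refinement, amplitude and
    latency quantification, supervised hearing-threshold estimation (logistic
    regression, gradient-boosted trees, convolutional network), unsupervised
    threshold estimation via functional principal component analysis and
    k-means clustering, and elastic time warping for curve registration.
    Includes a seeded synthetic ABR generator with ground-truth peak latencies,
    amplitudes and thresholds, CSV import/export in a documented dialect, and a
    command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    xgboost,
    glmnet,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
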