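Package: movart
Title: Head-Movement Artifact Detection and Rejection for Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and excises head-movement artifacts from
    electroencephalography (EEG) recordings by fusing spectral and
    time-domain EEG features with motion features from a head-mounted
    frontal camera. Per 128-sample epoch the package computes 12
    frequency-band magnitudes and 13 time-domain statistics (including
    the Hjorth activity, mobility and complexity parameters); per frame
    pair it computes pixel difference, Sobel-edge difference and
    pyramidal Lucas-Kanade motion-vector statistics. Feature streams are
    synchronized at camera cadence, reduced with Fisher-criterion linear
    discriminant analysis, and classified with a kernel support vector
    machine whose raw decision value is thresholded to minimise the mean
    of the per-class error rates. Includes a synthetic paired
    EEG-plus-video session generator, two-fold cross-validation by
    trial, ROC utilities, section-level rejection bookkeeping, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    MASS,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
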