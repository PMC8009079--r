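Package: harimage
Title: Human Activity Recognition from Accelerometer Co-Occurrence Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies human activities (jogging, walking, stair climbing,
    sitting, standing) from raw tri-axial smartphone accelerometer streams.
    Fixed-length sliding windows of the signal are encoded as multi-channel
    2D co-occurrence images ("HAR-Images"): for every pair of sensor axes, a
    quantized two-dimensional histogram of (axis-a, axis-b) sample pairs,
    with cell counts capped at 255 and normalized to [0, 1]. A small deep
    convolutional network trained on these images performs the
    classification. The package includes a reader for the WISDM v1.1 raw
    text format, a configurable synthetic accelerometer-stream generator for
    fully offline testing, reference implementations of the network's
    forward-pass operations, a compiled mini-batch trainer, one-vs-rest
    multi-class evaluation metrics, and a stratified k-fold
    cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
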