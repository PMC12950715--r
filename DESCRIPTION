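Package: tinyweednet
Title: Hardware-Efficient Lightweight Convolutional Networks for Weed Image
    Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements the TinyWeedNet family of lightweight convolutional
    neural networks for on-device weed image classification: a configurable
    architecture (strided stem, multi-scale convolution block, inverted
    residual blocks with channel attention, projection head) with exact
    closed-form and graph-walk complexity accounting (parameters,
    multiply-accumulate operations, serialized size), CPU training and
    evaluation with stratified splits and macro-F1 metrics, a photometric
    corruption suite for domain-shift robustness screening, a procedural
    synthetic weed-image generator for download-free testing, and export to
    a framework-independent exchange graph with an embedded-operator
    compatibility linter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
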