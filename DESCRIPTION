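Package: medleaf
Title: Medicinal Plant Leaf Classification with Dual Custom CNNs, Serial
    Feature Fusion and Binary Chimp Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for multi-class leaf-image
    classification built around two small custom convolutional networks (a
    residual-block design and an inverted-residual-block design), deep-feature
    extraction at the global average pooling layer, serial (column-wise)
    feature fusion with entropy-based ranking, wrapper feature selection by a
    binary variant of the Chimp Optimization Algorithm, a suite of shallow
    neural-network classifiers evaluated by stratified k-fold cross-validation,
    and Grad-CAM heatmaps for interpretability. Includes a parametric
    synthetic leaf-image generator and a planted-signal feature-table
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
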