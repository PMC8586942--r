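Package: tinysegnet
Title: Tiny-Object Semantic Segmentation Networks with Layer-Utilization
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and trains encoder-decoder convolutional networks
    (U-net, MultiResUNet and their reduced Half/Quarter variants) for
    segmenting tiny foreground objects, such as 3-10 pixel microplastic
    particles photographed on beach sand.  Provides a class-imbalance
    weighted binary cross-entropy loss, recall-weighted evaluation
    metrics (recall-weighted F1 and recall-weighted mIoU), exact
    parameter/FLOP/receptive-field accounting for any layer graph,
    an image tiling and augmentation pipeline with a synthetic
    sand-scene generator, five-fold cross-validation, and kernel
    weight-histogram analysis of per-stage layer utilization used to
    derive the reduced architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
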