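Package: angioquant
Title: Segmentation and Quantification of In Vitro Angiogenesis Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing phase-contrast micrographs of endothelial
    tube-formation (Matrigel) assays. Provides a synthetic-image generator
    with exact ground truth, readers for three-class label masks and CVAT
    polygon annotations, stratified dataset splitting, a multiclass focal
    loss with frequency-derived class weights, per-class and summary
    intersection-over-union metrics, pixelwise Cohen's kappa for
    inter-annotator agreement, small encoder-decoder segmentation networks
    (Unet, Unet++ and a DeepLabV3+-style variant) trainable on CPU with
    block-wise encoder fine-tuning, one-sided Wilcoxon signed-rank model
    comparison over cross-validation folds, and skeleton-graph
    quantification of vessel networks (branches, closed networks, nodes,
    lengths and areas).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    png,
    igraph,
    digest,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
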