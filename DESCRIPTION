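Package: mammotex
Title: Texture-Based Mammogram Analysis with a Hybrid BiLSTM-CNN Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computer-aided-diagnosis pipeline for two-class (normal versus
    abnormal) mammogram classification. Provides MIAS-style PGM/PNG image and
    annotation readers, shearlet-domain contrast enhancement on a Parseval
    frame, breast-region segmentation by variance-weighted ('improved') Otsu
    thresholding combined with Canny edge refinement, hybrid texture
    descriptors (first-order histogram statistics, gray-level co-occurrence
    and run-length matrices over four directions), a compiled convolutional
    network with a bidirectional LSTM head and optional handcrafted-feature
    fusion, stratified cross-validated evaluation with ablation support, and a
    seeded synthetic phantom generator so the whole pipeline can be exercised
    and tested without external image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
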