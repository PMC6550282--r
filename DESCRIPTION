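Package: echodl
Title: Data-Efficient Supervised and Semi-Supervised Deep Learning for
    Echocardiogram Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying data-efficient deep learning on
    echocardiogram-like images. Provides a seeded synthetic
    ultrasound-phantom generator with paired field-of-view and
    left-ventricle masks; a modified U-Net segmenter and a VGG-style
    convolutional classifier with resolution-dependent design rules,
    early stopping, two-stage transfer learning and ensembling; a
    semi-supervised generative adversarial network whose two-headed
    discriminator learns from labeled, unlabeled and generated images
    with a feature-matching generator; an end-to-end
    segmentation-masking-classification routing pipeline; and
    evaluation utilities with bootstrap confidence intervals. Networks
    run on a bundled CPU engine (RcppArmadillo convolution kernels)
    for fully seeded, single-threaded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
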