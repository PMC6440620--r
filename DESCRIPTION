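Package: bhcnet
Title: Small Squeeze-and-Excitation Residual Networks for Histopathology
    Image Classification
Version: 0.1.0
Authors@R:
    person("BHCNet", "Maintainers", email = "bhcnet@example.org",
           role = c("aut", "cre"))
Description: Builds and trains compact squeeze-and-excitation residual
    convolutional networks (the BHCNet family and a Cifar-scale SE-ResNet
    family) for benign/malignant and subtype classification of breast-cancer
    histopathology images. Provides the three SE-ResNet module variants
    (basic, bottleneck, and a factorized 1x3/3x1 "small" module) with
    analytic convolution parameter accounting, a Gauss-error-function
    learning-rate scheduler alongside step, step-R, cosine, and exponential
    comparators, Nesterov-momentum stochastic gradient descent, a
    BreakHis-layout dataset indexer with a deterministic synthetic texture
    generator, multiclass evaluation metrics (macro precision/recall/F,
    Matthews correlation, one-vs-rest AUC), and a command-line interface.
    All numerics run on CPU; convolutions are implemented in C++ via
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
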