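Package: pulsecnn
Title: Pulse-Wave-Pattern Classification with a Small Convolutional Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying arterial pulse-wave
    morphology into disease- and parameter-defined pattern classes. Provides
    a synthetic generator for multi-cycle pulse records built from
    percussion, tidal and dicrotic Gaussian components; wavelet denoising,
    foot-based cycle segmentation, 200-point resampling, 0-200 amplitude
    normalization and 200x200 rasterization of single cycles; cohort
    screening engines for disease-based and physiological-parameter-based
    classification criteria; a balanced dataset builder with PNG
    persistence; a compact 10-layer convolutional neural network (three
    convolution + max-pooling stages, dropout, two fully connected layers,
    softmax) trained with Adam and best-on-test checkpointing; and a
    confusion-matrix evaluation engine reporting per-class and overall
    precision, recall, F-measure and accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
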