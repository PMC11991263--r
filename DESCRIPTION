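Package: LIBSnet
Title: Multi-Scale Channel-Attention Neural Networks for Laser-Induced
    Breakdown Spectroscopy Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Preprocessing and classification of laser-induced breakdown
    spectroscopy (LIBS) emission spectra for origin authentication of
    medicinal plant material. Implements Savitzky-Golay smoothing with
    polynomial-reproducing edges, min-max normalization, iterative
    polynomial (ModPoly-style) baseline correction, wavelet denoising and
    SNR-based denoiser selection; a dual-stream multi-scale residual
    channel-attention 1-D convolutional network trained by SGD with a
    hand-derived backward pass; classical comparison models (1-D LeNet,
    modified AlexNet, ResNet-18, k-nearest neighbours, random forest,
    decision tree) under a common evaluation protocol; 1-D Grad-CAM
    saliency over wavelength; and a synthetic LIBS spectrum generator
    with grouped (tablet-level) replicate structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    Rcpp,
    class,
    randomForest,
    rpart,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
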