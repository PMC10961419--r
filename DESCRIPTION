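Package: leafcnn
Title: Lightweight Channel-Attention Convolutional Networks for Leaf Disease Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for training and evaluating lightweight
    ShuffleNetV2-style convolutional networks on plant leaf disease images.
    Implements channel split and channel shuffle units with optional residual
    shortcuts, an efficient dual-pool channel attention operator (average and
    standard-deviation pooled channel descriptors recalibrated through adaptive
    1-D convolutions) alongside SE, ECA and SRM comparators, multi-scale
    shallow and deep feature extraction blocks, the full SGD training recipe
    with a cosine-annealed learning rate, a stratified split and augmentation
    pipeline, robustness perturbations, macro precision/recall/F1 evaluation
    with per-crop aggregation, and a deterministic synthetic leaf-image
    generator so that every stage is testable at desk scale. The CNN engine
    (im2col convolution, depthwise convolution, batch normalisation, pooling
    and backpropagation) is implemented in the package with Rcpp kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    caret,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
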