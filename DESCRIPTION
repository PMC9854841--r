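Package: fossilnet
Title: Few-Shot Microfossil Image Recognition with Transfer Learning and
    Deep Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising rare microfossil taxa from stereo-microscope
    images when only a handful of training specimens per taxon exist. Provides
    a 34-layer deep residual network implemented on CPU via 'RcppArmadillo',
    configurable layer-freezing transfer-learning strategies (train the
    classifier head only, train a suffix of residual stages, or train all
    layers), the accompanying preprocessing pipeline (chroma-key background
    removal, affine augmentation, Gaussian noise, per-image standardisation),
    confusion-matrix evaluation with per-class and macro precision, recall and
    F1, a histogram-of-oriented-gradients plus support-vector-machine baseline,
    and a procedural generator of nine-class synthetic microfossil benchmarks
    together with a disjoint multi-class source domain for desk-scale
    pretraining, so that every stage of the pipeline is testable without
    external image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    e1071,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
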