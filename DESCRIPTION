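Package: msnet
Title: Stochastic-Pooling Convolutional Networks for Multiple Sclerosis
    Slice Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a 14-layer convolutional neural network with batch
    normalization, dropout and stochastic pooling for classifying 2-D
    grayscale brain MRI slices as multiple sclerosis or healthy control.
    Provides histogram-stretch contrast normalization, a deterministic
    five-transform data-augmentation scheme (rotation, scaling, Gaussian
    noise, translation, gamma correction), a hold-out multi-run evaluation
    harness with confusion-matrix metrics, an exact tied-ranks Wilcoxon
    signed-rank test for comparing pooling variants, and a seeded synthetic
    brain-slice generator with hyperintense plaque phantoms so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
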