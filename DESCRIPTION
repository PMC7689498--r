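Package: ichtriage
Title: Intracranial Haemorrhage Detection on Head CT with Monte Carlo
    Trained Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting intracranial haemorrhage
    (ICH) and classifying its subtypes on axial head-CT slice stacks using
    small fully-connected neural networks trained by derivative-free Monte
    Carlo random optimization (no backpropagation, no convolutions).
    Includes brain-window conversion of Hounsfield-valued slices,
    height-decile subdivision and slice summation, square expansion,
    flip augmentation, normal-average subtraction, ROC/AUC and weighted
    accuracy evaluation, and a synthetic head-phantom generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
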