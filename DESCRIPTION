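Package: thgqc
Title: Quality-Filtered Deep Learning Classification of Third Harmonic
    Generation Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for glioma versus non-tumor classification of label-free
    third harmonic generation (THG) microscopy images of brain tissue.
    Implements frequency-domain image quality statistics with a
    kurtosis-based noise exclusion rule for training data, a six-block
    fully-convolutional binary classifier accepting dynamic input sizes,
    case-level Monte-Carlo cross-validation with per-epoch minority
    oversampling and augmentation, Youden-calibrated evaluation
    (ROC/AUC, precision-recall/average precision, sensitivity,
    specificity), and sliding-window semantic overlays of tissue mosaics
    scored by per-class Jaccard index. A synthetic phantom generator
    renders THG-like tissue images, depth-degraded z-stacks, boundary
    mosaics and multi-case datasets with known ground truth, so the whole
    pipeline is testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
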