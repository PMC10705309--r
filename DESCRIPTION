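Package: rfsplus
Title: Region-Focused Selection Ensembles for Multi-Modal Brain Tumor
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for region-focused selection (RFS/RFS+) of brain tumor
    segmentation models on multi-modal MRI (T1, T1ce, T2, FLAIR). Implements
    a grid of U-net candidates crossing three segmentation approaches
    (multi-class, multi-label, binary) with two intensity normalization
    techniques (Z-score and Nyul piecewise-linear histogram standardization),
    selects the top three candidates per target region (enhancing tumor,
    tumor core, whole tumor) by internal Dice score, and combines them by
    weighted probability ensembling or mask union. Includes compact CPU
    implementations of the 2D/2.5D/3D U-net variants, Dice, 95th-percentile
    Hausdorff distance, sensitivity and specificity evaluation, and a
    synthetic multi-modal phantom generator so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
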