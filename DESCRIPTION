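Package: mammotex
Title: Texture-Based Mammography CAD Pipeline with Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end computer-aided-diagnosis pipeline for mammograms:
    PGM image input/output with mini-MIAS style metadata, label-artifact
    removal, five pre-processing combinations of median filtering, contrast
    limited adaptive histogram equalization (CLAHE) and unsharp masking,
    k-means intensity segmentation with pectoral-muscle removal, region-of-
    interest extraction, 22 gray-level co-occurrence matrix (GLCM) and 11
    gray-level run-length matrix (GLRLM) texture features averaged over four
    angles, correlation-based feature selection with per-feature ROC AUC
    screening, and benchmarking of six classifiers on normal/abnormal and
    benign/malignant tasks. A synthetic phantom-mammogram generator with
    ground-truth masks makes the whole analysis reproducible without any
    external image database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
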