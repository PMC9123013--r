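Package: morphodyn
Title: Morphodynamic Phenotyping of Tracked Cells from Label-Free Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A machine-learning phenomics pipeline for label-free time-lapse
    microscopy. Detects cells per frame with a Circular Hough Transform, links
    detections into single-cell tracks by minimum-cost (Munkres) assignment,
    groups tracks into spatial clusters, extracts luminance-robust 63x63 ROI
    sequences (inversion, mean-threshold background suppression, Gaussian
    windowing, histogram stretching and matching), encodes per-track phenotype
    dynamics as the temporal standard deviation of pluggable backbone feature
    signals, selects discriminative features by AUC quantiles, classifies
    tracks with SVM, boosted/random forests, diagonal LDA and KNN under
    leakage-free half-experiment-out cross-validation, and aggregates
    predictions by cluster-level majority voting. Includes a seeded synthetic
    video generator with ground truth, bias-sensitivity and single-time-point
    comparison protocols, a traditional shape + Haralick texture benchmark, and
    PCA score visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    e1071,
    randomForest,
    xgboost,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
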