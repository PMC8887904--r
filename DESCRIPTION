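Package: gmclass
Title: Convolutional Classification of Temporal Lobe Epilepsy from Grey-Matter Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for classifying left medial
    temporal lobe epilepsy against healthy controls from 2D coronal
    grey-matter density images. Provides a synthetic cohort generator with
    controllable medial-temporal and distributed atrophy, Gaussian (FWHM)
    smoothing, k-nearest-neighbour SMOTE oversampling of images,
    three-layer strided CNN and DAG-CNN classifiers with an addition layer,
    a repeated stratified grid-search evaluation protocol with a
    permuted-label null distribution and empirical p-values, subgroup
    metric reporting, and forward-activation-map visualization for feature
    localization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
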