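Package: fdpca
Title: Fuzzy Discriminant Principal Component Analysis for Electronic-Nose
    Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature extraction and classification for gas-sensor (electronic
    nose) array data. Implements fuzzy discriminant principal component
    analysis (FDPCA), which weights the between-class and total scatter
    matrices by fuzzy K-nearest-neighbour class memberships before extracting
    an orthogonal set of optimal discriminant vectors through deflated
    generalized eigenproblems, together with its crisp counterpart (DPCA) and
    ordinary PCA. Includes steady-state feature engineering from raw sensor
    response curves, min-max normalization, a KNN classifier with
    leave-one-out and repeated stratified k-fold cross-validation, a paired
    comparison of the three extractors, and a synthetic Gaussian sensor-array
    generator with controllable class overlap for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
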