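Package: ACOSelect
Title: Ant Colony Optimization Feature Selection for Medical Image
    Classification Pipelines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A computer-aided-diagnosis toolkit built around an ant colony
    optimization (ACO) feature selector guided by entropy-based symmetrical
    uncertainty. Features are extracted from images with a single-hidden-layer
    auto-encoder (or adapted from external convolutional backbones), ranked
    by feature-class relevance and feature-feature redundancy, and selected
    by a seeded ant colony search in either filter or wrapper mode. Includes
    image pre-processing (grayscale, bilinear resize, vectorization,
    stratified train/test splits), a pluggable classifier harness with a
    multiclass confusion-matrix metric suite (accuracy, sensitivity,
    specificity, precision, F1, misclassification rate, Matthews correlation
    coefficient), and synthetic data generators with planted ground truth so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    class,
    e1071,
    rpart,
    randomForest,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
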