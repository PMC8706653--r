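Package: harfusion
Title: Multi-Kernel Feature-Fusion Convolutional Networks for Human
    Activity Recognition from Six-Axis Inertial Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for waist-worn six-axis (accelerometer + gyroscope)
    human activity recognition. Provides readers and writers for
    fixed-length inertial window formats, raw-count conversion and
    min-max signal normalization fitted on training data only, sliding
    window segmentation, a three-branch one-dimensional convolutional
    feature-fusion classifier with kernel sizes 1/3/5 implemented from
    first principles (batch normalization, dropout, Adam with
    learning-rate plateau decay and early stopping), macro-averaged
    classification metrics with confusion matrices, stratified k-fold
    cross-validation, and a seeded synthetic inertial signal generator
    covering three gait-periodic and three near-static activities of
    daily living. Window collections are SummarizedExperiment objects,
    so standard Bioconductor subsetting and metadata idioms apply.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'harfusion-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'layers.R'
    'model.R'
    'training.R'
    'evaluation.R'
    'windowset.R'
    'signal_io.R'
    'preprocess.R'
    'simulate.R'
    'pipeline.R'
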