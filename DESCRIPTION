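Package: genesep
Title: Class-Separability Feature Selection and Classification for
    High-Dimensional Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filter-based feature selection for samples-by-genes expression
    matrices in the p >> n regime, using a per-gene class-separability score
    (the minimum over classes of the maximum within-class absolute deviation
    from the class mean), together with a uniform fit/predict classifier suite
    (random forest, decision tree, one-hot least-squares linear classifier,
    PCA+SVM, and a from-scratch LSTM), stratified train/test and k-fold
    evaluation with confusion-matrix metrics, a seeded synthetic expression
    simulator with planted informative genes, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    randomForest,
    rpart,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
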