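Package: drugsense
Title: Interpretable Binary Classification for Drug-Sensitivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end, leak-free binary classification pipelines for
    tabular pharmacogenomic data (e.g., log2-normalized expression profiles
    labelled sensitive/resistant). Provides chained feature selection
    (variance and MAD filters, PCA/random-projection/clustering/NMF-based
    reducers, forest-based selection, recursive and sequential elimination,
    model-X knockoffs with FDR control, correlation pruning, exhaustive
    small-subset search), normalization and class-imbalance resampling with
    strict test-set isolation, hyperparameter search with three engines and
    an overfitting-aware objective, a fifteen-algorithm model registry, a
    seven-metric composite evaluation score (NegLog2RMSL), global and local
    model interpretation (built-in, permutation, SHAP, LIME), and portable
    prediction bundles for standalone scoring of new samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    randomForest,
    ranger,
    xgboost,
    nnet,
    rpart,
    class,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
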