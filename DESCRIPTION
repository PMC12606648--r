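Package: ifptml
Title: Information Fusion and Perturbation-Theory Machine Learning for
    Multi-Condition Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds assay-condition-aware classifiers of compound bioactivity
    from heterogeneous preclinical assay tables. Raw activity values measured
    on mixed scales (IC50, Ki, inhibition percentages, ...) are binarized with
    per-measure desirability rules and cut-offs; Box-Jenkins moving-average
    expectations of molecular and protein descriptors are computed over
    boundary-condition groups and turned into perturbation-theory delta
    operators; a conditional reference function supplies the empirical prior
    probability of activity under each condition tuple. The resulting feature
    matrix feeds a linear discriminant scoring model with explicit
    coefficients and a suite of nonlinear classifiers (random forest, SVM,
    decision tree, k-nearest neighbours, gradient boosting, XGBoost), with
    variance/correlation feature filtering, stratified and cluster-based
    splits, randomized plus grid hyperparameter search, cross-validation,
    confusion-matrix metrics and ROC analysis. New compounds are screened
    across enumerated assay conditions and compared to a reference compound
    as relative predicted outcomes. A synthetic-data generator with planted
    effects makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    class,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    xgboost,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
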