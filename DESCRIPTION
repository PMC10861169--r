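Package: finlink
Title: Predictability and Imputation of Weighted Interareal Cortical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how predictable the weighted, directed, spatially
    embedded interareal cortical network is from partial retrograde
    tract-tracing data, and imputes the unobserved part. Implements
    out-neighbourhood classical link predictors, feature construction from
    fraction-of-labeled-neurons (FLN) weights and interareal distances,
    machine-learning classifiers and regressors behind a uniform contract,
    randomized row-wise k-fold cross-validation with ROC/AUC and relative
    mean-absolute-error evaluation, weight-class and regional predictability
    analyses, leave-one-out scaling curves, an exponential-distance-rule
    (EDR) network generator with configuration-model rewiring controls, and
    full-interareal-network (FIN) imputation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    caret,
    dplyr,
    e1071,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
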