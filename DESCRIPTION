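Package: splitbias
Title: Train/Test Split Sampling Bias Diagnostics for Limited Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the performance bias introduced by repeated stratified
    train/test splitting of a limited tabular cohort, as arises in radiomics
    studies of ductal carcinoma in situ (DCIS) upstaging. Provides a synthetic
    cohort generator with a known theoretical discriminability ceiling,
    prevalence-preserving stratified shuffle-splits with covariate balance
    monitoring, repeated stratified k-fold cross-validation with modal
    hyperparameter selection over regularized logistic regression and support
    vector machine grids, Mann-Whitney AUC and train-vs-test tradeoff
    statistics, and incremental-cohort learning curves with a median
    convergence diagnostic. All results are tidy tibbles with tidy(), glance()
    and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
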