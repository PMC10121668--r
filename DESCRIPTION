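Package: ensdm
Title: Ensemble Species Distribution Modelling with TSS-Weighted Averaging
    and Habitat-Change Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end ensemble species distribution modelling (SDM)
    pipeline for presence-only occurrence data on gridded environmental
    predictors: occurrence thinning and background sampling, Pearson
    collinearity pruning, a ten-family learner registry (GLM, GAM, GBM, RF,
    CTA, ANN, FDA, MARS, MaxEnt-style penalized logistic, and a surface
    range envelope) behind one fit/predict contract, repeated-split
    cross-validation with AUC and true skill statistic (TSS) scoring,
    TSS-weighted ensemble projection, five-class suitability
    classification, MAX_TSS binarization, permutation variable importance
    and contribution accounting, and current-versus-future habitat
    gain/loss change analysis. A synthetic-data module generates spatially
    autocorrelated predictor stacks with known logistic truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv,
    nnet,
    rpart,
    randomForest,
    xgboost,
    glmnet,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
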