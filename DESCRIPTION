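Package: dentage
Title: Dental Age Estimation from Staged Tooth Mineralization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic dental age estimation in juveniles from
    Demirjian mineralization stages (A-H) of the seven left mandibular
    permanent teeth. Provides score-table estimators (direct age-sum
    tables and maturity-score conversion), a non-intercept regression
    procedure that reweights a base score table to a local population,
    natively implemented tree-ensemble regressors (CART, gradient
    boosting, random forest, extra trees, AdaBoost.R2) and k-nearest
    neighbours, an evaluation battery (age deviation, capped mean
    absolute error, MSE/RMSE/R-squared, paired t-test, Cohen's kappa),
    and a synthetic cohort generator with known ground truth for
    method development and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    randomForest,
    xgboost,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
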