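Package: wristfeat
Title: Sleep and Wrist-Temperature Feature Engineering for Wearable Sensor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-day wrist-worn sensor recordings
    (tri-axial acceleration, skin temperature, ambient light) in clinical
    cohorts. Implements epoch-level preprocessing (ENMONZ activity summary,
    stillness-based non-wear detection, valid-day and valid-night filtering,
    low-temperature interpolation), extraction of novel sleep and circadian
    temperature features including normalized approximate entropy,
    relevance-redundancy-complementarity feature ranking with vote-based
    aggregation across leave-one-subject-out folds, fold-standardized
    L2-penalized logistic regression with leave-one-subject-out evaluation,
    AUC-weighted probabilistic ensembling, and an exploratory Spearman
    correlation screen against questionnaire outcomes. Ships a synthetic
    cohort generator with known planted structure so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
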