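Package: stabmark
Title: Stability Selection and Univariate Statistics for Multi-Modal
    Preclinical Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates multi-modal biomarker panels from 2x2 (genotype x
    treatment) preclinical cohorts. Provides a calibrated synthetic-cohort
    generator for case-control simulation with configurable standardized
    effect sizes; a univariate statistics pipeline with a priori 2-SD
    outlier filtering, normality- and variance-based test dispatch (ANOVA
    with Fisher's LSD planned contrasts, Welch's t, Mann-Whitney),
    two-stage adaptive Benjamini-Krieger-Yekutieli false discovery rate
    control, Cohen's d and noncentral-t post-hoc power; mono-exponential
    R2* relaxometry fitting from multi-echo gradient-echo decays; and a
    permutation-based stability-selection machine-learning procedure
    (linear-SVM or gradient-boosting feature ranking, distance-weighted
    3-nearest-neighbour or random-forest classification over nested
    feature subsets) that ranks biomarkers by top-15 occurrence and
    quantifies classification performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
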