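Package: urostrat
Title: Urine-Based Multigene qPCR Risk Stratification for Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for urine-based prostate-cancer risk
    stratification from a 14-gene qRT-PCR biomarker panel. Provides
    replicate averaging and beta-actin (reference-gene) normalization of
    cycle-threshold (Ct) values, a two-class quadratic-discriminant "D
    Score" classifier whose fitted form expands into an auditable
    constant/linear/pairwise-coefficient polynomial over the normalized
    expression values, per-gene differential-expression t-tests, and
    diagnostic performance evaluation (sensitivity, specificity, PPV and
    NPV with unclipped Wald confidence intervals; ROC curves with
    trapezoidal AUC and Hanley-McNeil intervals). A calibrated synthetic
    cohort generator simulates replicate-level raw Ct data with the
    two-group structure the analysis assumes, so the whole pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
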