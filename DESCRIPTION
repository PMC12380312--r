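Package: painrisk
Title: Questionnaire-Based Risk Modelling of Adolescent Musculoskeletal Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate a questionnaire-based risk model for
    chronic musculoskeletal pain (MSKP) in adolescents. Implements the MSKP
    severity index (banded pain-intensity ratings summed over four body
    regions), instrument scoring for mobile-dependency, sleep-disturbance and
    physical-activity questionnaires, a two-step feature-selection pipeline
    (Spearman-correlation screening followed by Lasso-regularized logistic
    regression under repeated stratified cross-validation with a
    median-nonzero retention rule), tertile risk stratification with held-out
    evaluation, and effect-size statistics (odds ratios per standard
    deviation, maximum odds ratios over a variable's range,
    Bonferroni-corrected confidence intervals, Wilson prevalence intervals).
    A Gaussian-copula synthetic cohort generator emulates the statistical
    structure of the survey so the full pipeline is testable without
    external data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
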