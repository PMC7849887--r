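Package: flutterscore
Title: Dynamic Comorbidity Risk Scores for Atrial Flutter Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and evaluating dynamic (baseline, follow-up and
    delta) comorbidity risk scores in atrial-flutter cohorts, including a
    reweighted CHA2DS2-VASc variant driven by standardized-difference balance
    diagnostics. Provides a seeded synthetic claims-style cohort generator,
    eligibility filtering with counterpart follow-up assignment,
    propensity-score estimation with greedy caliper matching, standardized
    mean difference balance tables, score-stratified relative risks, and
    discrimination comparison of score variants via AUC (DeLong), integrated
    discrimination improvement and category-free net reclassification
    improvement.
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
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
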