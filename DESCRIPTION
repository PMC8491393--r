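Package: oncomatch
Title: Molecular Matching Scores and Outcome Analyses for N-of-1 Precision Oncology Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how completely an individualized (N-of-1) drug
    combination targets a patient's tumor molecular profile via a rule-based
    Matching Score (0-100%), using an auditable drug-target knowledge base
    with synergy pairs, BRCA->platinum/PARP and TP53->VEGF-pathway special
    rules, hormone-receptor IHC matching, and an immunotherapy biomarker
    component (MSI, TMB, PD-L1). Provides cohort input/output in a
    documented tab-separated dialect, stratified disease-control contingency
    analyses with Fisher's exact test, ROC-based score cutoff selection,
    Kaplan-Meier and log-rank survival comparisons, logistic and Cox
    regression with a univariate P < 0.15 entry rule, grade-trend
    correlation, a TP53 sensitivity analysis, two-arm binomial power
    simulation, and a synthetic cohort generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
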