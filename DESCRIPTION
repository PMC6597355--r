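Package: ptsdcea
Title: Trial- and Model-Based Cost-Utility Analysis of Early Cognitive
    Therapy for Child and Adolescent PTSD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for the economic evaluation of an
    early trauma-focused cognitive therapy for children and adolescents with
    post-traumatic stress disorder (PTSD).  Provides a seeded synthetic trial
    cohort generator, SDQ-to-CHU-9D utility mapping and QALY accrual,
    resource-use costing with a unit-cost table, trial-horizon incremental
    analysis with conditional-regression imputation and covariate adjustment,
    a two-state (PTSD / PTSD-free) Markov cohort model with rate-to-probability
    conversion and annual discounting, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and one-way sensitivity analyses
    (therapist-training amortization, complete-case variant).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
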