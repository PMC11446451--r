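Package: claimscohort
Title: Chronic-Disease Incidence from Health-Insurance Claims and Enrollment Ledgers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A database-driven cohort workflow for estimating the incidence of
    chronic disease (type II diabetes mellitus in the reference analysis) from
    health-insurance claims linked to insured-person enrollment ledgers.
    Implements month-resolved continuity filtering of enrollment spells,
    claims-based case ascertainment with monotone carry-forward of disease
    status, fixed-denominator cumulative prevalence over a multi-year study
    window, incidence estimated as the least-squares slope of cumulative
    prevalence, and a denominator-weighted linear model pooling the annual
    increase over age and sex strata. Includes a synthetic claims-and-ledger
    generator with ground truth for validating every pipeline stage, and
    small-cell masking for disclosure-safe reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
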