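Package: erposcm
Title: Synthetic Control Evaluation of Extreme Risk Protection Order Laws
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for estimating the impact of state
    Extreme Risk Protection Order (ERPO, or "red flag") laws on state-month
    rates of firearm-violence incidents. Builds per-capita state-month outcome
    panels from incident-level records, applies effective-date and
    petition-uptake cohort filters, fits Abadie-Diamond-Hainmueller synthetic
    controls with a simplex-constrained weight solver and nested predictor
    importance optimization, and performs in-space placebo permutation
    inference with RMSPE-ratio ranking p-values, pre-period fit gating, and
    yearly effect summaries. Includes a factor-model simulator that generates
    complete ground-truth-annotated study inputs (incidents, covariates,
    petitions, policy catalogs) so the full pipeline is testable end to end.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
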