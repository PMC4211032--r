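Package: ambucea
Title: Cost-Effectiveness of Mobile-App Follow-Up After Ambulatory Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Societal-perspective cost-effectiveness model comparing
    mobile-app home monitoring with in-person clinic visits for the first
    postoperative month after ambulatory breast reconstruction.
    Implements a micro-costing ledger by payer stratum, incremental cost
    and effect with the not-reportable ICER rule, incremental net benefit
    at a quality-adjusted-life-year-derived willingness-to-pay, scenario
    and two-way deterministic sensitivity analyses, a seeded Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves and ICER-plane summaries, and a synthetic
    patient-cohort generator for end-to-end exercises of the model.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
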