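Package: streetpricer
Title: Street-Price Surveillance of Diverted Prescription Opioids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and cross-validating black-market street
    prices of diverted prescription opioids from heterogeneous report
    streams (crowdsourced submissions, law-enforcement surveys, and
    cryptomarket listings). Implements credibility filtering of
    crowdsourced reports (user-flagged price outliers, near-simultaneous
    same-IP duplicates), per-milligram geometric-mean price estimation
    with log-scale confidence intervals, Spearman rank-correlation
    cross-source validation with exact permutation p-values, and
    predicted relative potency (price ratio versus morphine) compared
    against clinical equianalgesic conversion factors. Includes a
    synthetic report generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
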