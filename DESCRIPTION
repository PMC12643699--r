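Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance analysis of
    spontaneous adverse event reports in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII format. Parses and deduplicates DEMO,
    DRUG, REAC, THER and INDI tables, normalizes drug names and MedDRA
    preferred terms, builds drug-event 2x2 contingency tables at preferred
    term and system organ class level, and scores them with four
    disproportionality algorithms: the reporting odds ratio (ROR), the
    proportional reporting ratio (PRR) with a Pearson chi-squared test, the
    Bayesian confidence propagation neural network information component
    (BCPNN IC), and the multi-item gamma Poisson shrinker (MGPS) empirical
    Bayes geometric mean (EBGM) with a fitted two-component gamma mixture
    prior. Time-to-onset samples are summarized and fitted with a
    two-parameter Weibull maximum-likelihood model whose shape parameter
    classifies the hazard as early-failure, random or wear-out. A seeded
    synthetic report generator with a ground-truth manifest makes every
    stage testable without access to the FAERS database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
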