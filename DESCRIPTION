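Package: libetbind
Title: Temporal Binding Analysis for Libet-Clock Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing temporal (intentional) binding experiments run
    with the rotating Libet clock: conversion between reported clock positions
    and event times with circular wrap-around, trial-level judgment errors with
    within-cell outlier trimming, participant-level action and tone binding
    scores with group outlier screening, two-way repeated-measures ANOVA with
    Mauchly's test and the Greenhouse-Geisser correction, Bonferroni-corrected
    pairwise contrasts, Cousineau within-subject confidence intervals, and
    Dienes half-normal Bayes factors with a ledger-based scheme that derives
    directional priors from a donor experiment's binding effects. A synthetic
    trial generator reproduces the statistical structure of published
    block-level summaries so the full pipeline can be exercised and calibrated
    without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
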