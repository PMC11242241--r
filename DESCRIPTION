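Package: asmsignals
Title: Signal Detection and Simulation for Spontaneous Adverse Event
    Reports on Anti-Seizure Medications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pharmacovigilance toolkit for spontaneous adverse drug
    reaction (ADR) reports on anti-seizure medications (ASMs).  Provides a
    report-level data model with a staged exclusion cascade and WHO-UMC
    causality filter, expansion of reports into ADR-drug pairs, 2x2
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio, Yates-corrected chi-square, shrunk information
    component with its IC025 lower credibility bound) under a conjunctive
    signal criterion, descriptive frequency tables and group contrasts
    (sodium-channel blockers vs other mechanisms), time-to-onset summaries
    with an 8-week sensitivity restriction, and a configurable synthetic
    spontaneous-report generator emulating a national reporting database
    with injected ground-truth drug-event associations.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
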