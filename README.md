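# asmsignals

Pharmacovigilance signal detection for spontaneous adverse-event reports on
anti-seizure medications (ASMs), with a synthetic report generator for
validating every stage of the analysis.

## The problem

National spontaneous-reporting systems (FAERS, VigiBase, KAERS, ...) collect
case reports of suspected adverse drug reactions (ADRs). Mining them for
drug-safety signals follows a well-established pipeline: clean the raw
reports, keep events whose WHO-UMC causality is at least *possible*, expand
each report into ADR-drug pairs (one suspected drug x one reported reaction,
coded as WHO-ART preferred terms nested in system organ classes), and test
each drug-event combination for disproportionate reporting. `asmsignals`
implements that pipeline for the 12 most-used ASMs, contrasted by mechanism:
sodium channel blockers (SCBs: carbamazepine, lacosamide, lamotrigine,
oxcarbazepine, phenytoin, topiramate, valproate) versus non-SCBs
(clonazepam, gabapentin, levetiracetam, phenobarbital, pregabalin). It is
aimed at pharmacoepidemiologists who want a reproducible, testable version
of this analysis and a ground-truth simulator to probe its operating
characteristics, since raw national databases are rarely redistributable.

## The statistics

For each drug-event combination a 2x2 table is built over the pair
universe (`a` = target drug & event, `b` = target drug & other events,
`c` = other drugs & event, `d` = the rest):

- **ROR** = `ad / bc`, with the 95% Woolf (log-normal) interval
  `exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`; Haldane–Anscombe +0.5
  correction when a cell is zero.
- **PRR** = `(a/(a+b)) / (c/(c+d))`.
- **χ²** — Pearson chi-square with Yates continuity correction.
- **IC / IC025** — shrunk information component `log2((a+0.5)/(E+0.5))`
  with `E = (a+b)(a+c)/N`, and the closed-form lower 95% credibility bound
  `IC − 3.3(a+0.5)^(−1/2) − 2(a+0.5)^(−3/2)`.

A **signal** is a combination meeting all five gates: `n ≥ 3`, `ROR ≥ 2`,
`PRR ≥ 2`, `χ² ≥ 4`, `IC025 ≥ 0` (each threshold configurable via
`signal_criteria()`). Descriptive modules add stratified frequency tables,
SCB vs non-SCB contrasts (chi-square / Fisher's exact), the
sexual/reproductive SOC subset analysis (WHO-ART codes 1410/1420/1500/1600),
and time-to-onset medians with an 8-week sensitivity restriction.

The synthetic generator (`sim_config()`, `kaers_like_config()`,
`generate_reports()`) emulates a KAERS-like database: configurable drug and
event reporting marginals, injected drug-event associations (multiplicative
rate multipliers with a closed-form **induced ROR**), stratum mixes, onset
delay distributions per mechanism group x SOC, date missingness, and
report anomalies that exercise the cleaning cascade.

## Worked example

```r
library(asmsignals)

cfg     <- kaers_like_config(n_reports = 20000, seed = 42)
reports <- generate_reports(cfg)
cleaned <- clean_reports(reports)
cleaned$ledger
#> <cleaning_ledger>
#>   input_reports                  20000
#>   excluded_incomplete            84
#>   excluded_not_suspected         132
#>   excluded_logical_error         90
#>   excluded_missing_ae            80
#>   retained_reports               19614

pairs <- expand_pairs(cleaned$reports) |> filter_causality()  # 23,599 pairs

screen <- screen_signals(pairs, level = "soc")
glance(screen)
#>   n_pairs n_combinations n_signals n_inestimable
#> 1   23599            144         5            24
dplyr::filter(tidy(screen), signal)
#>            drug   group                         event   n estimate conf.low conf.high  ic025
#> 1 carbamazepine     SCB Skin and appendages disorders 584     3.12     2.78      3.51  0.863
#> 2    clonazepam NON_SCB         Psychiatric disorders 327     3.87     3.38      4.42  1.308
#> 3   lamotrigine     SCB Skin and appendages disorders 775     8.11     7.12      9.23  1.420
#> 4 oxcarbazepine     SCB Skin and appendages disorders 461     4.58     3.97      5.28  1.113
#> 5     phenytoin     SCB Skin and appendages disorders 243     3.12     2.61      3.72  0.817
```

The screen recovers exactly the associations the generator injected:
elevated skin-disorder reporting for the aromatic sodium channel blockers
and psychiatric reporting for clonazepam, with their RORs, Woolf intervals
and IC025 all clearing the conjunctive criterion.

```r
onset_comparison(pairs, pt_codes = c(10001, 10002, 10003)) |>
  dplyr::filter(mode == "within_8_weeks")
#>     pt_name median_scb (Q1, Q3) median_nonscb (Q1, Q3) median_diff
#> 1      Rash          4  (1, 7)              2  (0, 3)           2
#> 2  Pruritus          3  (1, 8)              1  (0, 3)           2
#> 3 Urticaria          4  (1, 8)              1  (0, 3)           3
```

Skin reactions start a median 2-3 days later under SCBs than non-SCBs —
the delayed-hypersensitivity pattern the generator encodes. A full run
(`run_pipeline()`) writes every artifact (pairs, ledger, frequency tables,
signal screens, onset table, manifest) to a directory, and
`render_tables()` assembles them into display-rounded markdown tables.

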