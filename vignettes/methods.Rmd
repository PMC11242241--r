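---
title: "Methods: disproportionality screening of spontaneous ASM reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous ASM reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmsignals)
```

## Scope and data model

`asmsignals` analyzes spontaneous adverse-event reports on twelve
anti-seizure medications (ASMs), contrasted by mechanism: sodium channel
blockers (SCBs) versus other mechanisms (non-SCBs). A dataset is three
relational tables — reports, drug entries, adverse-event entries — tied by
`report_id` (`report_set()`). Reactions are coded at two levels of a
WHO-ART-style hierarchy: preferred terms (PT) nested in system organ
classes (SOC). The unit of analysis is the **ADR–drug pair**: one suspected
study drug combined with one reported reaction from the same report
(`expand_pairs()`), the full cross-product when a report carries several
suspected study drugs. We treat the cross-product as the expansion rule
because each suspected drug is, by the reporter's assessment, a candidate
cause of each reaction; this multiplies ambiguous multi-drug reports into
several pairs and is therefore conservative for none and anticonservative
for all drugs involved — a known, documented property of pair-based
disproportionality, flagged for sensitivity analysis rather than hidden.

## Cleaning cascade

`clean_reports()` excludes reports in a fixed order, counting each report
once at its first failing stage, so the ledger is well defined:

1. *Incomplete data* — national databases do not publish their
   incompleteness predicate, so ours is the strictest reading that cannot
   discard analyzable rows: sex unknown **and** age missing **and** no
   event entry carrying a PT code. It is replaceable
   (`incomplete_predicate` argument) because it is a declared substitute,
   not a reconstruction.
2. *No suspected study drug.*
3. *Logical errors* — an onset date before a suspected study drug's start
   date, or a report date before a start date. Negative onset intervals
   are treated as logical errors; consequently cleaned pairs never carry
   negative `onset_days`.
4. *No adverse-event information.*

Conservation (`input = retained + Σ excluded`) is enforced by the
`cleaning_ledger()` constructor itself. Events whose causality is below
*possible* on the WHO-UMC scale are then removed at the **pair** level
(`filter_causality()`), because each reported event carries its own
assessment.

## Disproportionality statistics

For a drug-or-group selector and a PT/SOC selector, every pair in the
loaded universe falls in exactly one cell of the 2×2 (`make_contingency()`).
The comparator is always *all other pairs in the loaded universe*: screens
of an ASM-only dataset are within-ASM contrasts. Restricting the universe
before screening yields within-group contrasts instead; this choice is the
user's, not hidden in the statistics.

- **ROR** `= ad/bc` with the Woolf interval
  `exp(ln ROR ± z·√(1/a+1/b+1/c+1/d))`. Zero cells: Haldane–Anscombe +0.5
  on all four cells, applied only when a zero occurs (`correction =
  "auto"`), always, or never (then a zero cell is a classed error). The
  correction state is returned with every estimate.
- **PRR** `= (a/(a+b))/(c/(c+d))`, same continuity rule.
- **χ²**: Pearson with Yates continuity correction,
  `Σ max(0, |O−E|−0.5)²/E` — the convention classically attached to PRR
  signal criteria. A zero marginal gives 0 with a warning rather than an
  error, so screens of sparse universes degrade gracefully. `yates =
  FALSE` switches the correction off.
- **IC / IC025**: the disproportionality literature has several IC
  variants and the upstream analysis does not state which it used, so we
  adopt the WHO-style shrunk observed-to-expected component,
  `IC = log2((a+0.5)/(E+0.5))` with `E = (a+b)(a+c)/N`, and the published
  closed-form approximation of the 2.5th posterior percentile,
  `IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`. The +0.5 shrinkage is
  intrinsic; the Haldane correction is never additionally applied to IC's
  raw counts. Because the variant is a substitute, per-drug IC values from
  other systems are not comparable figure-for-figure; the conjunctive
  criterion below is the meaningful output.
- **Signal** (`detect_signal()`): `n ≥ 3` and `ROR ≥ 2` and `PRR ≥ 2` and
  `χ² ≥ 4` and `IC025 ≥ 0`, thresholds inclusive and configurable
  (`signal_criteria()`). No multiple-testing adjustment is applied — the
  conjunctive gate is the traditional, sole filter — which is a known
  limitation: family-wise error over hundreds of screened combinations is
  uncontrolled, and `screen_signals()` output retains full precision so
  users can post-process.

Descriptive contrasts use `stats::chisq.test` / `stats::fisher.test`;
Fisher's exact is chosen for 2×2 tables with any expected cell below 5, and
its two-sided p-value is the conventional sum of probabilities of tables no
more probable than the observed one.

## Time to onset

`onset_days` is the onset date minus the suspected drug's start date;
pairs missing either date are excluded from onset summaries. Day-0 onsets
are valid observations. The 8-week sensitivity restriction keeps
`onset_days ≤ 56` — the boundary is included because "within 8 weeks"
includes its endpoint. Quartiles interpolate linearly between order
statistics (`stats::quantile` type 7, the R default); the convention
matters with integer day data and is stated here because printed tables
rarely declare theirs.

## The synthetic generator

Real national pharmacovigilance extracts are not redistributable, so every
stage is validated against `generate_reports()` operating on a
`sim_config()`. Per report: strata are drawn from categorical mixes; one
suspected drug from the drug marginals; the number of events is
`1 + Geometric(p)` truncated at 6 with mean ≈ 1.3 (spontaneous reports
typically list one, occasionally several reactions); events are drawn from
the base event marginals with the drug's injected multipliers applied
multiplicatively and renormalized, duplicates within a report collapsed;
start dates are uniform over 2012–2021; onset = start + a delay drawn per
(mechanism group × SOC); each date is blanked independently (default
0.0625 per date, giving ≈ 12% of pairs with a missing interval); small
report-level anomaly rates plant incomplete, logically erroneous and
event-less reports so the cascade always has work to do. All draws flow
from a single seeded generator: identical config and seed reproduce the
dataset byte for byte.

**Ground truth.** The induced ROR of a configured (drug, PT) cell is
computed in closed form from the joint distribution — including the
event-count distribution and within-report deduplication — via
`expected_pair_masses()`; `calibrate_signal_multiplier()` root-finds the
multiplier achieving a target induced ROR. Anomalies, date blanking and
the causality filter thin all cells uniformly and leave the induced ROR
unchanged, which is what makes the closed form exact. With all multipliers
at 1 the induced ROR is exactly 1 everywhere.

**Delay model.** Delays are discrete day counts: geometric with success
probability `1 − 0.5^{1/(m+1)}`, which gives an exact median of `m` days,
plus a 7% long-latency tail (57 days + Geometric(0.02)) so that the 8-week
restriction is informative. `kaers_like_config()` sets the skin-SOC
medians to 3 days (SCB) versus 1 day (non-SCB) — the delayed
type-2-hypersensitivity pattern — and 0 elsewhere.

**What `kaers_like_config()` emulates.** Stratum mixes approximating the
2012–2021 reporting profile (female 62.7%, age > 60 45.8%, pharmacists the
largest reporter group, ≈ 6.1% serious, causality mostly *possible*);
drug marginals proportioned so SCBs are ≈ 31.6% of pairs; elevated
skin-event multipliers for carbamazepine, lamotrigine, oxcarbazepine,
phenytoin and phenobarbital, neurological multipliers for gabapentin and
pregabalin, and a psychiatric multiplier for clonazepam; a small decoy
(non-study) drug share exercising exclusion stage 2. Event marginals are
set so that even the rarest common-term cell keeps an expected count ≳ 10
at 50,000 reports — a deliberate design floor, because the Woolf interval
is asymptotic. **What it does not emulate:** duplicate submissions,
secular reporting trends, reporter-dependent coding habits, drug–drug
interaction signals, true incidence (spontaneous counts are reporting
rates, not risks). Passing recovery tests on this generator therefore
demonstrates the pipeline's correctness and the estimator's operating
characteristics, not the clinical truth of any specific real-world signal.

**Null calibration.** `null_sim_config()` removes all injections and
restricts the vocabulary to the common terms (base weight ≥ 0.012). The
calibration check asks whether the per-pair 95% intervals cover 1 about
95% of the time; we gate the *pooled* empirical coverage over all
(drug, PT) cells and replicates at ≥ 0.90, and additionally report the
worst per-pair rate. A strict "every pair individually ≥ 90/100" gate
would be dominated by binomial noise: a perfectly calibrated cell fails it
with probability ≈ 0.6%, so across ~300 cells some failure is near-certain
even for an exact estimator.

## Problem sizes and numerical choices

Simulation-based checks use 100 replicates of 50,000 reports for signal
recovery (injected association calibrated to induced ROR 5) and null
coverage, and 100 seeds of 20,000 reports for the onset-delay sign — sizes
chosen to put Monte-Carlo error well below the tested margins (the
standard error of the mean recovered ROR is ≈ 0.4% of its value) while a
full run stays in the minutes range on one CPU. Probability vectors must
sum to 1 within 1e-9; multiplier calibration solves to 1e-10 on the log
scale. Ages are floored to integer years before binning; an age of exactly
60 falls in ">60" (decade labels are exhaustive). Top-N reaction lists
break count ties alphabetically by PT name so output is deterministic.
Display rounding (1-decimal percentages, 2-decimal ratios) is half-up,
applied only in renderers — stored results keep full precision, and
rounded values never feed back into computation.

## Degenerate inputs

Empty pair universes are classed errors; a selector matching nothing
yields a legal table with zero cells; screens flag inestimable rows
(`estimable = FALSE`) instead of failing; single-category group contrasts
return a "not applicable" result; onset summaries of zero usable pairs
return `n_used = 0` with NA quartiles. Cleaning never fails — pathological
reports are excluded and counted.
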