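#' Simulation configuration for a spontaneous-reporting database
#'
#' Describes a generative model for KAERS-like spontaneous reports: marginal
#' drug and event reporting probabilities, injected drug-event associations
#' (multiplicative rate multipliers on the event distribution conditional on
#' the drug, renormalized), stratum mixes (sex, age, reporter, causality,
#' seriousness), per-(mechanism group x SOC) onset-delay distributions, date
#' missingness, and small report-level anomaly rates that exercise the
#' cleaning cascade.
#'
#' The per-report number of adverse events is `1 + Geometric(adr_geom_prob)`
#' truncated at `max_adrs` (default mean about 1.3).  Onset delays are
#' discrete day counts: geometric with a configurable median per
#' (group x SOC), plus a small long-latency tail so that an 8-week
#' restriction is informative.
#'
#' @param n_reports number of reports to generate (>= 1).
#' @param drug_marginals named probability vector over drug names; names
#'   absent from `catalog` act as decoy (non-study) drugs.
#' @param event_marginals named probability vector; names are PT codes
#'   present in `dictionary`.
#' @param injected_signals tibble with columns `drug_name`, `pt_code`,
#'   `multiplier` (rate multipliers, >= 0; 1 = no association).
#' @param sex_probs,age_group_probs,reporter_probs,causality_probs named
#'   probability vectors over the respective vocabularies.
#' @param serious_prob probability a report is serious.
#' @param serious_category_probs named probability vector over
#'   seriousness categories (sampled for serious reports).
#' @param adr_geom_prob geometric success probability for the event count.
#' @param max_adrs cap on events per report.
#' @param delay_medians tibble with columns `group`, `soc_code`,
#'   `median_days` overriding `default_delay_median` for specific cells.
#' @param default_delay_median median onset delay (days) where no override.
#' @param delay_tail_prob probability of a long-latency delay.
#' @param delay_tail_offset,delay_tail_geom_prob long-latency delay is
#'   `offset + Geometric(prob)` days.
#' @param date_start,date_end drug start dates are uniform in this window.
#' @param date_missing_prob probability each start/onset date is blanked.
#' @param anomaly_probs named vector `c(incomplete=, logical_error=,
#'   missing_ae=)` of report-level anomaly rates (may sum to < 1).
#' @param dictionary a [term_dictionary()] covering `event_marginals`.
#' @param catalog a [asm_catalog()].
#' @param seed integer root seed; all draws flow from one generator.
#' @return an object of class `sim_config`.
#' @seealso [kaers_like_config()], [null_sim_config()], [generate_reports()]
#' @export
sim_config <- function(n_reports,
                       drug_marginals,
                       event_marginals,
                       injected_signals = NULL,
                       sex_probs = c(male = 0.45, female = 0.45, unknown = 0.1),
                       age_group_probs = NULL,
                       reporter_probs = NULL,
                       causality_probs = NULL,
                       serious_prob = 0.06,
                       serious_category_probs = NULL,
                       adr_geom_prob = 1 / 1.3,
                       max_adrs = 6L,
                       delay_medians = NULL,
                       default_delay_median = 0,
                       delay_tail_prob = 0.07,
                       delay_tail_offset = 57L,
                       delay_tail_geom_prob = 0.02,
                       date_start = as.Date("2012-01-01"),
                       date_end = as.Date("2021-12-31"),
                       date_missing_prob = 0.0625,
                       anomaly_probs = c(incomplete = 0, logical_error = 0,
                                         missing_ae = 0),
                       dictionary = default_term_dictionary(),
                       catalog = asm_catalog(),
                       seed = 1L) {
  if (!is.numeric(n_reports) || n_reports < 1) {
    abort_asm("n_reports must be >= 1", class = "asm_config_error")
  }
  assert_prob(drug_marginals, "drug_marginals")
  assert_prob(event_marginals, "event_marginals")
  if (is.null(names(drug_marginals)) || is.null(names(event_marginals))) {
    abort_asm("drug_marginals and event_marginals must be named",
              class = "asm_config_error")
  }
  if (!all(as.integer(names(event_marginals)) %in% dictionary$pt_code)) {
    abort_asm("event_marginals contain PT codes absent from the dictionary",
              class = "asm_config_error")
  }
  if (is.null(injected_signals)) {
    injected_signals <- tibble(drug_name = character(), pt_code = integer(),
                               multiplier = numeric())
  }
  injected_signals <- as_tibble(injected_signals)
  assert_cols(injected_signals, c("drug_name", "pt_code", "multiplier"),
              "injected_signals")
  if (any(injected_signals$multiplier < 0)) {
    abort_asm("injected multipliers must be >= 0", class = "asm_config_error")
  }
  if (is.null(age_group_probs)) {
    age_group_probs <- setNames(rep(1 / 8, 8), age_group_levels())
  }
  if (is.null(reporter_probs)) {
    reporter_probs <- setNames(rep(1 / 6, 6), reporter_levels())
  }
  if (is.null(causality_probs)) {
    causality_probs <- c(unclassified = 0.01, unassessable = 0.01,
                         unlikely = 0.03, possible = 0.7, probable = 0.23,
                         certain = 0.02)
  }
  if (is.null(serious_category_probs)) {
    serious_category_probs <-
      setNames(rep(1 / 6, 6), seriousness_categories())
  }
  assert_prob(sex_probs, "sex_probs")
  assert_prob(age_group_probs, "age_group_probs")
  assert_prob(reporter_probs, "reporter_probs")
  assert_prob(causality_probs, "causality_probs")
  assert_prob(serious_category_probs, "serious_category_probs")
  stopifnot(serious_prob >= 0, serious_prob <= 1,
            adr_geom_prob > 0, adr_geom_prob <= 1, max_adrs >= 1,
            date_missing_prob >= 0, date_missing_prob <= 1,
            delay_tail_prob >= 0, delay_tail_prob < 1,
            date_start <= date_end)
  if (any(anomaly_probs < 0) || sum(anomaly_probs) > 1) {
    abort_asm("anomaly_probs must be nonnegative and sum to <= 1",
              class = "asm_config_error")
  }
  if (is.null(delay_medians)) {
    delay_medians <- tibble(group = character(), soc_code = integer(),
                            median_days = numeric())
  }
  structure(list(
    n_reports = as.integer(n_reports),
    drug_marginals = drug_marginals,
    event_marginals = event_marginals,
    injected_signals = injected_signals,
    sex_probs = sex_probs,
    age_group_probs = age_group_probs,
    reporter_probs = reporter_probs,
    causality_probs = causality_probs,
    serious_prob = serious_prob,
    serious_category_probs = serious_category_probs,
    adr_geom_prob = adr_geom_prob,
    max_adrs = as.integer(max_adrs),
    delay_medians = as_tibble(delay_medians),
    default_delay_median = default_delay_median,
    delay_tail_prob = delay_tail_prob,
    delay_tail_offset = as.integer(delay_tail_offset),
    delay_tail_geom_prob = delay_tail_geom_prob,
    date_start = date_start,
    date_end = date_end,
    date_missing_prob = date_missing_prob,
    anomaly_probs = anomaly_probs,
    dictionary = dictionary,
    catalog = catalog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d reports, %d drugs, %d event terms, ",
    "%d injected signal(s), seed %d\n"),
    x$n_reports, length(x$drug_marginals), length(x$event_marginals),
    nrow(x$injected_signals), x$seed))
  invisible(x)
}

# geometric success probability giving an exact median of m days
geom_prob_for_median <- function(m) 1 - 0.5^(1 / (m + 1))

# event distribution conditional on each drug: base marginals times the
# drug's injected multipliers, renormalized.  Rows = drugs, cols = PT codes.
conditional_event_probs <- function(config) {
  drugs <- names(config$drug_marginals)
  pts <- as.integer(names(config$event_marginals))
  m <- matrix(rep(config$event_marginals, each = length(drugs)),
              nrow = length(drugs), dimnames = list(drugs, pts))
  inj <- config$injected_signals
  if (nrow(inj) > 0) {
    di <- match(normalize_drug(inj$drug_name), drugs)
    ei <- match(inj$pt_code, pts)
    keep <- !is.na(di) & !is.na(ei)
    m[cbind(di[keep], ei[keep])] <-
      m[cbind(di[keep], ei[keep])] * inj$multiplier[keep]
  }
  sweep(m, 1, rowSums(m), "/")
}

# pmf of the per-report event count K = min(1 + Geom(p), max_adrs)
event_count_pmf <- function(config) {
  p <- config$adr_geom_prob
  k <- seq_len(config$max_adrs)
  pk <- p * (1 - p)^(k - 1)
  pk[config$max_adrs] <- (1 - p)^(config$max_adrs - 1)
  pk
}

#' Expected ADR-drug pair masses under a simulation configuration
#'
#' For each (study drug, PT) combination, the expected per-report probability
#' that the cleaned, expanded dataset contains that pair, computed in closed
#' form from the configured joint distribution (drug marginals renormalized
#' over study drugs, conditional event distribution after injected
#' multipliers, and the per-report event-count distribution with
#' within-report deduplication).  Report-level anomalies, the causality
#' filter and date missingness thin all cells uniformly and therefore do not
#' change ratios of these masses.
#'
#' @param config a [sim_config()].
#' @return a tibble with columns `drug_name`, `pt_code`, `mass`.
#' @export
expected_pair_masses <- function(config) {
  q <- conditional_event_probs(config)
  study <- intersect(rownames(q), config$catalog$drug_name)
  q <- q[study, , drop = FALSE]
  pd <- config$drug_marginals[study]
  pd <- pd / sum(pd)
  pk <- event_count_pmf(config)
  # P(event e appears at least once among K iid draws) for each cell
  appear <- matrix(0, nrow(q), ncol(q), dimnames = dimnames(q))
  for (k in seq_along(pk)) appear <- appear + pk[k] * (1 - (1 - q)^k)
  mass <- appear * pd
  tibble(
    drug_name = rep(rownames(mass), times = ncol(mass)),
    pt_code = rep(as.integer(colnames(mass)), each = nrow(mass)),
    mass = as.vector(mass)
  )
}

#' Induced reporting odds ratio of a configured association
#'
#' The true ROR induced by the generative model for one (drug, PT) cell,
#' computed from the expected pair masses: `(a d) / (b c)` on the expected
#' 2x2 over the study-drug pair universe.  With all multipliers at 1 the
#' induced ROR is exactly 1 for every cell.
#'
#' @param config a [sim_config()].
#' @param drug_name,pt_code the target cell.
#' @return a single number.
#' @export
induced_ror <- function(config, drug_name, pt_code) {
  m <- expected_pair_masses(config)
  drug_name <- normalize_drug(drug_name)
  tot <- sum(m$mass)
  a <- sum(m$mass[m$drug_name == drug_name & m$pt_code == pt_code])
  rd <- sum(m$mass[m$drug_name == drug_name])
  ce <- sum(m$mass[m$pt_code == pt_code])
  b <- rd - a
  cc <- ce - a
  d <- tot - a - b - cc
  (a * d) / (b * cc)
}

#' Calibrate an injected multiplier to a target induced ROR
#'
#' Solves (by root finding on the log multiplier) for the rate multiplier of
#' one (drug, PT) cell such that the ROR induced by the generative model
#' equals `target_ror`, holding every other configured signal fixed.
#'
#' @param config a [sim_config()].
#' @param drug_name,pt_code the cell to calibrate.
#' @param target_ror desired induced ROR (> 0).
#' @return the updated `sim_config` with the calibrated multiplier appended;
#'   the achieved multiplier is in `config$injected_signals`.
#' @export
calibrate_signal_multiplier <- function(config, drug_name, pt_code,
                                        target_ror) {
  stopifnot(target_ror > 0)
  drug_name <- normalize_drug(drug_name)
  with_mult <- function(lambda) {
    cfg <- config
    inj <- cfg$injected_signals %>%
      filter(!(normalize_drug(.data$drug_name) == !!drug_name &
                 .data$pt_code == !!pt_code))
    cfg$injected_signals <- bind_rows(
      inj, tibble(drug_name = drug_name, pt_code = as.integer(pt_code),
                  multiplier = lambda))
    cfg
  }
  f <- function(loglam) {
    induced_ror(with_mult(exp(loglam)), drug_name, pt_code) - target_ror
  }
  sol <- uniroot(f, interval = c(log(1e-4), log(1e4)), tol = 1e-10)
  with_mult(exp(sol$root))
}

#' Ground truth for configured associations
#'
#' The induced ROR for every injected (drug, PT) signal of a configuration,
#' for use as simulation ground truth when checking recovery.
#'
#' @param config a [sim_config()].
#' @return tibble with columns `drug_name`, `pt_code`, `multiplier`,
#'   `induced_ror`.
#' @export
ground_truth <- function(config) {
  inj <- config$injected_signals
  if (nrow(inj) == 0) {
    return(tibble(drug_name = character(), pt_code = integer(),
                  multiplier = numeric(), induced_ror = numeric()))
  }
  inj %>%
    mutate(induced_ror = purrr::map2_dbl(
      .data$drug_name, .data$pt_code,
      function(d, e) induced_ror(config, d, e)))
}

#' Generate a synthetic spontaneous-report dataset
#'
#' Samples a [report_set()] from a [sim_config()]: strata from the category
#' mixes, one suspected drug per report from the drug marginals, one or more
#' adverse events from the drug-conditional event distribution (injected
#' multipliers applied multiplicatively, then renormalized; duplicate events
#' within a report collapsed), drug start dates uniform in the configured
#' window, onset dates offset by (group x SOC) delay draws, independent date
#' blanking, and the configured report-level anomalies.  The same
#' configuration and seed always reproduce the identical dataset.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a [report_set()].
#' @export
generate_reports <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  report_id <- sprintf("R%07d", seq_len(n))

  sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
  ag <- sample(names(config$age_group_probs), n, TRUE, config$age_group_probs)
  lo <- c("00-09" = 0, "10-19" = 10, "20-29" = 20, "30-39" = 30,
          "40-49" = 40, "50-59" = 50, ">60" = 60)[ag]
  hi <- ifelse(ag == ">60", 90, lo + 10)
  age_years <- ifelse(ag == "Unknown", NA_real_,
                      floor(runif(n, ifelse(is.na(lo), 0, lo),
                                  ifelse(is.na(hi), 1, hi))))
  reporter <- sample(names(config$reporter_probs), n, TRUE,
                     config$reporter_probs)
  serious <- runif(n) < config$serious_prob
  ser_cat <- character(n)
  if (any(serious)) {
    ser_cat[serious] <- sample(names(config$serious_category_probs),
                               sum(serious), TRUE,
                               config$serious_category_probs)
  }
  drug <- sample(names(config$drug_marginals), n, TRUE, config$drug_marginals)
  start_num <- floor(runif(n, as.numeric(config$date_start),
                           as.numeric(config$date_end) + 1))

  # adverse-event slots
  k <- pmin(1L + rgeom(n, config$adr_geom_prob), config$max_adrs)
  rep_idx <- rep(seq_len(n), k)
  slot_drug <- drug[rep_idx]
  q <- conditional_event_probs(config)
  pts <- as.integer(colnames(q))
  ev <- integer(length(rep_idx))
  for (d in rownames(q)) {
    sl <- which(slot_drug == d)
    if (length(sl) > 0) ev[sl] <- sample(pts, length(sl), TRUE, q[d, ])
  }
  keep <- !duplicated(paste(rep_idx, ev, sep = "_"))
  rep_idx <- rep_idx[keep]
  ev <- ev[keep]
  m <- length(ev)

  causality <- sample(names(config$causality_probs), m, TRUE,
                      config$causality_probs)

  # onset delays by (mechanism group of the drug) x (SOC of the event)
  grp <- config$catalog$group[match(drug[rep_idx], config$catalog$drug_name)]
  soc <- config$dictionary$soc_code[match(ev, config$dictionary$pt_code)]
  med <- rep(config$default_delay_median, m)
  dm <- config$delay_medians
  if (nrow(dm) > 0) {
    key <- paste(grp, soc, sep = "|")
    ov <- match(key, paste(dm$group, dm$soc_code, sep = "|"))
    med[!is.na(ov)] <- dm$median_days[ov[!is.na(ov)]]
  }
  delay <- rgeom(m, geom_prob_for_median(med))
  tail <- runif(m) < config$delay_tail_prob
  if (any(tail)) {
    delay[tail] <- config$delay_tail_offset +
      rgeom(sum(tail), config$delay_tail_geom_prob)
  }
  onset_num <- start_num[rep_idx] + delay

  # report date: latest onset plus a short reporting lag
  max_onset <- rep(start_num, 1)
  agg <- tapply(onset_num, rep_idx, max)
  max_onset[as.integer(names(agg))] <- agg
  report_num <- max_onset + rgeom(n, 0.2)

  # report-level anomalies (mutually exclusive, first matching band)
  u <- runif(n)
  p1 <- config$anomaly_probs[["incomplete"]]
  p2 <- config$anomaly_probs[["logical_error"]]
  p3 <- config$anomaly_probs[["missing_ae"]]
  a_inc <- u < p1
  a_log <- u >= p1 & u < p1 + p2
  a_mae <- u >= p1 + p2 & u < p1 + p2 + p3

  pt_col <- ev
  if (any(a_inc)) {
    sex[a_inc] <- "unknown"
    age_years[a_inc] <- NA_real_
    pt_col[a_inc[rep_idx]] <- NA_integer_
  }
  if (any(a_log)) {
    first_row <- match(which(a_log), rep_idx)
    first_row <- first_row[!is.na(first_row)]
    onset_num[first_row] <- start_num[rep_idx[first_row]] -
      (1 + rgeom(length(first_row), 0.1))
  }

  # independent date blanking
  start_miss <- runif(n) < config$date_missing_prob
  onset_miss <- runif(m) < config$date_missing_prob

  adr_keep <- !a_mae[rep_idx]
  adrs <- tibble(
    report_id = report_id[rep_idx[adr_keep]],
    pt_code = pt_col[adr_keep],
    onset_date = as.Date(ifelse(onset_miss[adr_keep], NA,
                                onset_num[adr_keep]),
                         origin = "1970-01-01"),
    causality = causality[adr_keep]
  )
  drugs <- tibble(
    report_id = report_id,
    drug_name = drug,
    role = "suspected",
    start_date = as.Date(ifelse(start_miss, NA, start_num),
                         origin = "1970-01-01")
  )
  reports <- tibble(
    report_id = report_id,
    sex = sex,
    age_years = age_years,
    reporter = reporter,
    serious = serious,
    serious_categories = ser_cat,
    report_date = as.Date(report_num, origin = "1970-01-01")
  )
  report_set(reports, drugs, adrs)
}

# base (un-normalized) event weights of the study-like vocabulary
kaers_event_weights <- function() {
  d <- default_term_dictionary()
  w <- c(
    "Rash" = 0.085, "Pruritus" = 0.045, "Urticaria" = 0.030,
    "Rash Erythematous" = 0.012,
    "Dizziness" = 0.150, "Somnolence" = 0.085, "Headache" = 0.032,
    "Tremor" = 0.020, "Paresthesia" = 0.015,
    "Insomnia" = 0.025, "Agitation" = 0.015, "Depression" = 0.018,
    "Aggressive Reaction" = 0.012, "Amnesia" = 0.012,
    "Nausea" = 0.075, "Vomiting" = 0.040, "Constipation" = 0.035,
    "Dyspepsia" = 0.028, "Mouth Dry" = 0.030, "Diarrhea" = 0.015,
    "Hepatic Enzymes Increased" = 0.022,
    "Leucopenia" = 0.012, "Thrombocytopenia" = 0.012,
    "Fever" = 0.025, "Asthenia" = 0.020, "Face Edema" = 0.013,
    "Sexual Function Abnormal" = 0.0008, "Menstrual Disorder" = 0.0015,
    "Amenorrhea" = 0.0008, "Drug Exposure In Pregnancy" = 0.0002,
    "Psychomotor Development Impaired" = 0.0003
  )
  setNames(as.numeric(w), d$pt_code[match(names(w), d$pt_name)])
}

#' Study-like simulation configuration
#'
#' A configuration whose stratum mixes approximate the reporting
#' characteristics of the emulated national database over 2012-2021
#' (female about 62.7%, age over 60 about 45.8%, pharmacists the most
#' frequent reporters, about 6% serious reports, causality mostly
#' "possible"), whose skin-SOC onset-delay medians are 3 days for sodium
#' channel blockers versus 1 day for other mechanisms, and which injects
#' elevated skin-event multipliers for carbamazepine, lamotrigine,
#' oxcarbazepine, phenytoin (and phenobarbital), elevated neurological
#' multipliers for gabapentin and pregabalin, and an elevated psychiatric
#' multiplier for clonazepam.
#'
#' @param n_reports number of reports (default 50,000).
#' @param seed root seed.
#' @return a [sim_config()].
#' @export
kaers_like_config <- function(n_reports = 50000, seed = 1L) {
  d <- default_term_dictionary()
  ew <- kaers_event_weights()
  pt_of <- function(name) d$pt_code[match(name, d$pt_name)]
  skin_pts <- d$pt_code[d$soc_code == 100L]
  cns_pts <- pt_of(c("Dizziness", "Somnolence"))
  psych_pts <- d$pt_code[d$soc_code == 500L]
  inj <- bind_rows(
    tidyr::expand_grid(drug_name = "carbamazepine", pt_code = skin_pts,
                       multiplier = 4),
    tidyr::expand_grid(drug_name = "lamotrigine", pt_code = skin_pts,
                       multiplier = 10),
    tidyr::expand_grid(drug_name = "oxcarbazepine", pt_code = skin_pts,
                       multiplier = 6),
    tidyr::expand_grid(drug_name = "phenytoin", pt_code = skin_pts,
                       multiplier = 3.5),
    tidyr::expand_grid(drug_name = "phenobarbital", pt_code = skin_pts,
                       multiplier = 4.5),
    tidyr::expand_grid(drug_name = "valproate", pt_code = skin_pts,
                       multiplier = 1.5),
    tidyr::expand_grid(drug_name = "gabapentin", pt_code = cns_pts,
                       multiplier = 1.5),
    tidyr::expand_grid(drug_name = "pregabalin", pt_code = cns_pts,
                       multiplier = 2.5),
    tidyr::expand_grid(drug_name = "clonazepam", pt_code = psych_pts,
                       multiplier = 3),
    tidyr::expand_grid(drug_name = "topiramate", pt_code = psych_pts,
                       multiplier = 1.5)
  )
  sim_config(
    n_reports = n_reports,
    drug_marginals = c(
      carbamazepine = 0.055, lacosamide = 0.020, lamotrigine = 0.048,
      oxcarbazepine = 0.035, phenytoin = 0.022, topiramate = 0.040,
      valproate = 0.096,
      clonazepam = 0.055, gabapentin = 0.200, levetiracetam = 0.075,
      phenobarbital = 0.015, pregabalin = 0.333,
      ibuprofen = 0.006  # decoy, excluded by the cleaning cascade
    ),
    event_marginals = ew / sum(ew),
    injected_signals = inj,
    sex_probs = c(male = 0.348, female = 0.627, unknown = 0.025),
    age_group_probs = c("00-09" = 0.032, "10-19" = 0.034, "20-29" = 0.058,
                        "30-39" = 0.076, "40-49" = 0.113, "50-59" = 0.198,
                        ">60" = 0.458, "Unknown" = 0.031),
    reporter_probs = c(clinician = 0.209, pharmacist = 0.392, nurse = 0.319,
                       other_medical = 0.005, consumer = 0.056,
                       unknown = 0.019),
    causality_probs = c(unclassified = 0.005, unassessable = 0.007,
                        unlikely = 0.030, possible = 0.700,
                        probable = 0.242, certain = 0.016),
    serious_prob = 0.061,
    serious_category_probs = {
      w <- c(death = 65, life_threatening = 130, hospitalization = 1633,
             disability = 31, congenital_anomaly = 2,
             other_medical_event = 1240)
      w / sum(w)
    },
    delay_medians = tibble(
      group = c("SCB", "NON_SCB"),
      soc_code = c(100L, 100L),
      median_days = c(3, 1)
    ),
    anomaly_probs = c(incomplete = 0.004, logical_error = 0.005,
                      missing_ae = 0.004),
    seed = seed
  )
}

#' Null calibration configuration
#'
#' The study-like configuration with every injected multiplier removed (so
#' the true ROR is exactly 1 for all cells) and the event vocabulary
#' restricted to the common terms (base weight at least 0.012), keeping the
#' expected count of every (drug, PT) cell large enough (roughly >= 10 at
#' 50,000 reports) for the asymptotic Woolf interval whose coverage the null
#' calibration evaluates.
#'
#' @param n_reports number of reports (default 50,000).
#' @param seed root seed.
#' @return a [sim_config()].
#' @export
null_sim_config <- function(n_reports = 50000, seed = 1L) {
  cfg <- kaers_like_config(n_reports = n_reports, seed = seed)
  ew <- kaers_event_weights()
  ew <- ew[ew >= 0.012]
  cfg$event_marginals <- ew / sum(ew)
  cfg$injected_signals <- cfg$injected_signals[0, ]
  cfg
}
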