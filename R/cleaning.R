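#' Staged exclusion cascade for spontaneous reports
#'
#' Applies the report-level exclusion cascade, in a fixed order so that a
#' report failing several rules is counted exactly once, at its first failing
#' stage:
#'
#' 1. **incomplete data** - by default, sex unknown AND age missing AND no
#'    adverse-event entry carrying a PT code (the strictest reading that
#'    cannot discard analyzable rows; override via `incomplete_predicate`);
#' 2. **no suspected study drug** - no drug entry with role `"suspected"`
#'    whose name is in the catalog;
#' 3. **logical errors** - an adverse-event onset date earlier than a
#'    suspected study drug's start date (both present), or a report date
#'    earlier than a suspected study drug's start date;
#' 4. **no adverse-event information** - no adverse-event entries at all.
#'
#' Cleaning is total: pathological inputs are excluded, never fatal.
#'
#' @param x a [report_set()].
#' @param catalog a [asm_catalog()].
#' @param incomplete_predicate optional function taking the report set and
#'   returning a logical vector (one element per report row) flagging
#'   incomplete reports; replaces the default predicate.
#' @return a list with elements `reports` (the retained [report_set()]) and
#'   `ledger` (a `cleaning_ledger`).
#' @export
clean_reports <- function(x, catalog = asm_catalog(),
                          incomplete_predicate = NULL) {
  stopifnot(inherits(x, "report_set"))
  rep_ids <- x$reports$report_id
  n_in <- length(rep_ids)

  has_pt <- rep_ids %in% x$adrs$report_id[!is.na(x$adrs$pt_code)]
  if (is.null(incomplete_predicate)) {
    s1 <- x$reports$sex == "unknown" & is.na(x$reports$age_years) & !has_pt
  } else {
    s1 <- as.logical(incomplete_predicate(x))
    stopifnot(length(s1) == n_in)
  }

  susp <- x$drugs %>%
    filter(.data$role == "suspected",
           .data$drug_name %in% catalog$drug_name)
  s2 <- !(rep_ids %in% susp$report_id)

  # logical errors, judged against suspected study drugs
  pair_dates <- susp %>%
    inner_join(x$adrs, by = "report_id", relationship = "many-to-many") %>%
    filter(!is.na(.data$start_date), !is.na(.data$onset_date),
           .data$onset_date < .data$start_date)
  rep_dates <- susp %>%
    inner_join(select(x$reports, "report_id", "report_date"),
               by = "report_id") %>%
    filter(!is.na(.data$start_date), !is.na(.data$report_date),
           .data$report_date < .data$start_date)
  s3 <- rep_ids %in% c(pair_dates$report_id, rep_dates$report_id)

  s4 <- !(rep_ids %in% x$adrs$report_id)

  stage <- rep(0L, n_in)            # 0 = retained
  stage[s4] <- 4L
  stage[s3] <- 3L
  stage[s2] <- 2L
  stage[s1] <- 1L

  keep <- stage == 0L
  retained_ids <- rep_ids[keep]
  retained <- report_set(
    x$reports[keep, ],
    filter(x$drugs, .data$report_id %in% retained_ids),
    filter(x$adrs, .data$report_id %in% retained_ids)
  )
  ledger <- cleaning_ledger(
    input_reports = n_in,
    excluded_incomplete = sum(stage == 1L),
    excluded_not_suspected = sum(stage == 2L),
    excluded_logical_error = sum(stage == 3L),
    excluded_missing_ae = sum(stage == 4L),
    retained_reports = sum(keep)
  )
  list(reports = retained, ledger = ledger)
}

#' Cleaning ledger
#'
#' Per-stage accounting of the exclusion cascade.  Conservation holds by
#' construction: `input_reports` equals the retained count plus the sum of
#' the excluded stages.  Pair-level counts (`pairs_generated`,
#' `pairs_after_causality_filter`) are `NA` until the expansion and causality
#' stages fill them in.
#'
#' @param input_reports,excluded_incomplete,excluded_not_suspected,excluded_logical_error,excluded_missing_ae,retained_reports,pairs_generated,pairs_after_causality_filter stage counts.
#' @return an object of class `cleaning_ledger`.
#' @export
cleaning_ledger <- function(input_reports, excluded_incomplete,
                            excluded_not_suspected, excluded_logical_error,
                            excluded_missing_ae, retained_reports,
                            pairs_generated = NA_integer_,
                            pairs_after_causality_filter = NA_integer_) {
  out <- list(
    input_reports = as.integer(input_reports),
    excluded_incomplete = as.integer(excluded_incomplete),
    excluded_not_suspected = as.integer(excluded_not_suspected),
    excluded_logical_error = as.integer(excluded_logical_error),
    excluded_missing_ae = as.integer(excluded_missing_ae),
    retained_reports = as.integer(retained_reports),
    pairs_generated = as.integer(pairs_generated),
    pairs_after_causality_filter = as.integer(pairs_after_causality_filter)
  )
  excl <- out$excluded_incomplete + out$excluded_not_suspected +
    out$excluded_logical_error + out$excluded_missing_ae
  if (out$input_reports != out$retained_reports + excl) {
    abort_asm("ledger does not conserve reports", class = "asm_integrity_error")
  }
  if (!is.na(out$pairs_generated) && !is.na(out$pairs_after_causality_filter) &&
      out$pairs_after_causality_filter > out$pairs_generated) {
    abort_asm("causality filter cannot increase pair count",
              class = "asm_integrity_error")
  }
  structure(out, class = "cleaning_ledger")
}

#' @export
print.cleaning_ledger <- function(x, ...) {
  cat("<cleaning_ledger>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Expand cleaned reports into ADR-drug pairs
#'
#' The unit of analysis: one row per (suspected study drug x adverse event)
#' combination within a report, the full cross-product when a report carries
#' several suspected study drugs.  SOC is resolved through the dictionary;
#' events with unknown or missing PT codes are dropped with a logged count
#' (attribute `dropped_unknown_pt`).  `onset_days` is the onset date minus
#' the drug start date, missing iff either date is missing; negative
#' intervals never occur in cleaned input (they are logical errors excluded
#' upstream).
#'
#' @param x a cleaned [report_set()].
#' @param dictionary a [term_dictionary()].
#' @param catalog a [asm_catalog()].
#' @return a tibble of ADR-drug pairs with columns `report_id`, `drug_name`,
#'   `group`, `pt_code`, `pt_name`, `soc_code`, `soc_name`, `causality`,
#'   `sex`, `age_group`, `reporter`, `serious`, `serious_categories`,
#'   `onset_days`.
#' @export
expand_pairs <- function(x, dictionary = default_term_dictionary(),
                         catalog = asm_catalog()) {
  stopifnot(inherits(x, "report_set"))
  susp <- x$drugs %>%
    filter(.data$role == "suspected",
           .data$drug_name %in% catalog$drug_name) %>%
    select("report_id", "drug_name", "start_date") %>%
    distinct()
  adrs <- x$adrs
  n_na_pt <- sum(is.na(adrs$pt_code))
  adrs <- filter(adrs, !is.na(.data$pt_code))
  known <- adrs$pt_code %in% dictionary$pt_code
  n_unknown <- sum(!known)
  if (n_unknown > 0 || n_na_pt > 0) {
    inform(sprintf(
      "dropped %d ADR entr(ies) with unknown and %d with missing PT codes",
      n_unknown, n_na_pt))
  }
  adrs <- adrs[known, ]

  pairs <- susp %>%
    inner_join(adrs, by = "report_id", relationship = "many-to-many") %>%
    mutate(group = classify_drug(.data$drug_name, catalog)) %>%
    left_join(as_tibble(dictionary), by = "pt_code") %>%
    left_join(select(x$reports, "report_id", "sex", "age_years", "reporter",
                     "serious", "serious_categories"),
              by = "report_id") %>%
    mutate(
      age_group = assign_age_group(.data$age_years),
      onset_days = as.integer(.data$onset_date - .data$start_date)
    ) %>%
    select("report_id", "drug_name", "group", "pt_code", "pt_name",
           "soc_code", "soc_name", "causality", "sex", "age_group",
           "reporter", "serious", "serious_categories", "onset_days") %>%
    arrange(.data$report_id, .data$drug_name, .data$pt_code)
  attr(pairs, "dropped_unknown_pt") <- n_unknown + n_na_pt
  pairs
}

#' Filter pairs by WHO-UMC causality
#'
#' Retains pairs whose causality is at or above the given minimum category.
#' Under the default minimum (`"possible"`) this keeps certain, probable and
#' possible - the conventional definition of an adverse drug reaction.
#' Applied at the pair level because each reported event carries its own
#' assessment.
#'
#' @param pairs a pair tibble from [expand_pairs()].
#' @param minimum minimum causality category (see [causality_levels()]).
#' @return the filtered pair tibble.
#' @export
filter_causality <- function(pairs, minimum = "possible") {
  minimum <- as_causality(minimum)
  if (is.na(minimum)) {
    abort_asm("invalid minimum causality", class = "asm_config_error")
  }
  filter(pairs, as_causality(.data$causality) >= minimum)
}
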