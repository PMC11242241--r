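#' A set of spontaneous case reports
#'
#' Bundles the three relational tables that make up a spontaneous-reporting
#' extract: one row per report (`reports`), one row per drug entry (`drugs`),
#' and one row per adverse-event entry (`adrs`).  This is the tabular
#' equivalent of a list of case reports with nested drug/reaction records.
#'
#' @param reports tibble with columns `report_id`, `sex`, `age_years`,
#'   `reporter`, `serious` (logical), `serious_categories`
#'   (semicolon-joined, `""` = none), `report_date` (Date).
#' @param drugs tibble with columns `report_id`, `drug_name`, `role`
#'   (`"suspected"`/`"concomitant"`), `start_date` (Date).
#' @param adrs tibble with columns `report_id`, `pt_code` (integer),
#'   `onset_date` (Date), `causality`.
#' @return an object of class `report_set` (a named list of three tibbles).
#' @export
report_set <- function(reports, drugs, adrs) {
  reports <- as_tibble(reports)
  drugs <- as_tibble(drugs)
  adrs <- as_tibble(adrs)
  assert_cols(reports, c("report_id", "sex", "age_years", "reporter",
                         "serious", "serious_categories", "report_date"),
              "reports table")
  assert_cols(drugs, c("report_id", "drug_name", "role", "start_date"),
              "drugs table")
  assert_cols(adrs, c("report_id", "pt_code", "onset_date", "causality"),
              "adrs table")
  if (anyDuplicated(reports$report_id)) {
    abort_asm("duplicate report_id in reports table",
              class = "asm_integrity_error")
  }
  if (any(reports$age_years < 0, na.rm = TRUE)) {
    abort_asm("age_years must be nonnegative", class = "asm_validation_error")
  }
  orphans <- c(setdiff(drugs$report_id, reports$report_id),
               setdiff(adrs$report_id, reports$report_id))
  if (length(orphans) > 0) {
    abort_asm(sprintf("drug/adr rows reference unknown report_id(s): %s",
                      paste(unique(orphans), collapse = ", ")),
              class = "asm_integrity_error")
  }
  structure(list(reports = canon_tbl(reports), drugs = canon_tbl(drugs),
                 adrs = canon_tbl(adrs)),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports, %d drug entries, %d ADR entries\n",
              nrow(x$reports), nrow(x$drugs), nrow(x$adrs)))
  invisible(x)
}

#' Number of reports in a report set
#' @param x a [report_set()].
#' @export
n_reports <- function(x) nrow(x$reports)

# map free-text enumeration tokens to a fixed vocabulary; unknown -> "unknown"
map_token <- function(x, vocabulary, field) {
  x <- tolower(trimws(x))
  x[is.na(x) | x == ""] <- "unknown"
  bad <- setdiff(unique(x), vocabulary)
  if (length(bad) > 0) {
    warn(sprintf("%s token(s) not in vocabulary mapped to \"unknown\": %s",
                 field, paste(bad, collapse = ", ")))
    x[x %in% bad] <- "unknown"
  }
  x
}

iso_date <- function(x, field) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  ok <- is.na(x) | grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (!all(ok)) {
    abort_asm(sprintf("%s: dates must be ISO-8601 (YYYY-MM-DD); offending: %s",
                      field, paste(head(unique(x[!ok]), 3), collapse = ", ")),
              class = "asm_schema_error")
  }
  out <- as.Date(x, format = "%Y-%m-%d")
  if (any(!is.na(x) & is.na(out))) {
    abort_asm(sprintf("%s: invalid calendar date(s)", field),
              class = "asm_schema_error")
  }
  out
}

read_csv_quiet <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE)
}

#' Read a report set from delimited files
#'
#' Reads `reports.csv`, `drugs.csv` and `adrs.csv` from a directory (UTF-8,
#' comma-separated, header row mandatory, empty string = missing).  Unknown
#' enumeration tokens (sex, reporter, role) are mapped to `"unknown"` with a
#' warning; PT codes are kept verbatim (unknown codes are counted and dropped
#' later, at pair expansion).  Dates must be ISO-8601.
#'
#' @param dir directory containing the three files.
#' @return a [report_set()].
#' @export
read_reports <- function(dir) {
  paths <- file.path(dir, c("reports.csv", "drugs.csv", "adrs.csv"))
  for (p in paths) {
    if (!file.exists(p)) {
      abort_asm(sprintf("missing input file: %s", p), class = "asm_io_error")
    }
  }
  rep_raw <- read_csv_quiet(paths[1])
  drug_raw <- read_csv_quiet(paths[2])
  adr_raw <- read_csv_quiet(paths[3])
  assert_cols(rep_raw, c("report_id", "sex", "age_years", "reporter",
                         "serious", "serious_categories", "report_date"),
              "reports.csv")
  assert_cols(drug_raw, c("report_id", "drug_name", "role", "start_date"),
              "drugs.csv")
  assert_cols(adr_raw, c("report_id", "pt_code", "onset_date", "causality"),
              "adrs.csv")

  if (anyDuplicated(rep_raw$report_id)) {
    rep_raw <- distinct(rep_raw)
    if (anyDuplicated(rep_raw$report_id)) {
      abort_asm("duplicate report_id with conflicting fields in reports.csv",
                class = "asm_integrity_error")
    }
  }

  reports <- rep_raw %>%
    mutate(
      sex = map_token(.data$sex, sex_levels(), "sex"),
      age_years = suppressWarnings(as.numeric(
        ifelse(.data$age_years == "", NA, .data$age_years))),
      reporter = map_token(.data$reporter, reporter_levels(), "reporter"),
      serious = tolower(trimws(.data$serious)) %in% c("true", "1", "yes"),
      serious_categories = ifelse(is.na(.data$serious_categories), "",
                                  .data$serious_categories),
      report_date = iso_date(.data$report_date, "reports.csv report_date")
    )
  drugs <- drug_raw %>%
    mutate(
      drug_name = normalize_drug(.data$drug_name),
      role = map_token(.data$role, role_levels(), "role"),
      start_date = iso_date(.data$start_date, "drugs.csv start_date")
    )
  adrs <- adr_raw %>%
    mutate(
      pt_code = suppressWarnings(as.integer(
        ifelse(.data$pt_code == "", NA, .data$pt_code))),
      onset_date = iso_date(.data$onset_date, "adrs.csv onset_date"),
      causality = as.character(as_causality(
        ifelse(trimws(.data$causality) == "", "unclassified", .data$causality)))
    )
  report_set(reports, drugs, adrs)
}

#' Write a report set to delimited files
#'
#' Inverse of [read_reports()]: writes `reports.csv`, `drugs.csv` and
#' `adrs.csv` (empty string for missing values, ISO-8601 dates) so that a
#' write/read round trip is the identity on canonical report sets.
#'
#' @param x a [report_set()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(x, dir) {
  stopifnot(inherits(x, "report_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) {
    readr::write_csv(df, file.path(dir, file), na = "", progress = FALSE)
  }
  w(x$reports, "reports.csv")
  w(x$drugs, "drugs.csv")
  w(x$adrs, "adrs.csv")
  invisible(dir)
}

#' Read a term dictionary from CSV
#'
#' Expects columns `pt_code`, `pt_name`, `soc_code`, `soc_name`.
#'
#' @param path path to `dictionary.csv`.
#' @return a [term_dictionary()].
#' @export
read_dictionary <- function(path) {
  raw <- read_csv_quiet(path)
  assert_cols(raw, c("pt_code", "pt_name", "soc_code", "soc_name"),
              "dictionary.csv")
  term_dictionary(raw)
}

#' Write a term dictionary to CSV
#'
#' @param dictionary a [term_dictionary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  readr::write_csv(as_tibble(dictionary), path, na = "", progress = FALSE)
  invisible(path)
}
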