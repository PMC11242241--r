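#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> clean -> expand -> causality filter ->
#' describe -> screen -> onset in order and writes every artifact to
#' `out_dir`: the four delimited input files, `pairs.csv`, `ledger.json`,
#' `characteristics.csv`, `soc_distribution.csv`, `top_adrs_scb.csv`,
#' `top_adrs_nonscb.csv`, `sexrep.csv`, `signals_pt.csv`, `signals_soc.csv`,
#' `onset.csv`, `tests.json`, a provenance `run_config.json` and a
#' `manifest.json` listing every output with its row count.  All randomness
#' is confined to the generator, so a rerun with the same inputs and seed
#' is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()] used to simulate input when `in_dir` is
#'   `NULL`.
#' @param in_dir optional directory with existing `reports.csv`,
#'   `drugs.csv`, `adrs.csv` to analyze instead of simulating.
#' @param seed seed for simulation (defaults to `config$seed`).
#' @param min_causality minimum causality category retained.
#' @param criteria a [signal_criteria()].
#' @param dictionary,catalog the vocabulary and drug catalog.
#' @param top_n number of top reactions to tabulate.
#' @return invisibly, a list with the in-memory results (`pairs`, `ledger`,
#'   `screen_pt`, `screen_soc`, `onset`, `manifest`, ...).
#' @export
run_pipeline <- function(out_dir,
                         config = kaers_like_config(n_reports = 5000),
                         in_dir = NULL,
                         seed = NULL,
                         min_causality = "possible",
                         criteria = signal_criteria(),
                         dictionary = default_term_dictionary(),
                         catalog = asm_catalog(),
                         top_n = 20) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(in_dir)) {
    seed <- seed %||% config$seed
    rs <- generate_reports(config, seed = seed)
    dictionary <- config$dictionary
    catalog <- config$catalog
    write_reports(rs, out_dir)
    write_dictionary(dictionary, file.path(out_dir, "dictionary.csv"))
    gt <- ground_truth(config)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         digits = NA)
  } else {
    rs <- read_reports(in_dir)
  }

  cleaned <- clean_reports(rs, catalog = catalog)
  pairs_all <- expand_pairs(cleaned$reports, dictionary = dictionary,
                            catalog = catalog)
  pairs <- filter_causality(pairs_all, minimum = min_causality)
  ledger <- cleaning_ledger(
    input_reports = cleaned$ledger$input_reports,
    excluded_incomplete = cleaned$ledger$excluded_incomplete,
    excluded_not_suspected = cleaned$ledger$excluded_not_suspected,
    excluded_logical_error = cleaned$ledger$excluded_logical_error,
    excluded_missing_ae = cleaned$ledger$excluded_missing_ae,
    retained_reports = cleaned$ledger$retained_reports,
    pairs_generated = nrow(pairs_all),
    pairs_after_causality_filter = nrow(pairs)
  )
  inform(paste0(
    "cleaning: ", ledger$input_reports, " reports -> ",
    ledger$retained_reports, " retained (incomplete ",
    ledger$excluded_incomplete, ", no suspected study drug ",
    ledger$excluded_not_suspected, ", logical error ",
    ledger$excluded_logical_error, ", missing AE ",
    ledger$excluded_missing_ae, "); pairs ", ledger$pairs_generated,
    " -> ", ledger$pairs_after_causality_filter,
    " after causality filter"))

  characteristics <- characteristics_table(pairs)
  socs <- soc_distribution(pairs)
  top_scb <- top_adrs(pairs, group = "SCB", n = top_n)
  top_non <- top_adrs(pairs, group = "NON_SCB", n = top_n)
  sexrep <- sexual_reproductive_analysis(pairs)
  screen_pt <- screen_signals(pairs, level = "pt", criteria = criteria)
  screen_soc <- screen_signals(pairs, level = "soc", criteria = criteria)
  onset <- onset_comparison(pairs)
  tests <- list(
    sex = glance(compare_groups(pairs, "sex")),
    age_group = glance(compare_groups(pairs, "age_group")),
    seriousness = glance(compare_groups(
      mutate(pairs, seriousness = ifelse(.data$serious, "Yes", "No")),
      "seriousness")),
    sexual_reproductive = glance(sexrep$test)
  )

  wcsv <- function(df, file) {
    readr::write_csv(df, file.path(out_dir, file), na = "", progress = FALSE)
    file
  }
  files <- c(
    wcsv(pairs, "pairs.csv"),
    wcsv(characteristics, "characteristics.csv"),
    wcsv(socs, "soc_distribution.csv"),
    wcsv(top_scb, "top_adrs_scb.csv"),
    wcsv(top_non, "top_adrs_nonscb.csv"),
    wcsv(sexrep$by_term, "sexrep.csv"),
    wcsv(screen_pt, "signals_pt.csv"),
    wcsv(screen_soc, "signals_soc.csv"),
    wcsv(onset, "onset.csv")
  )
  jsonlite::write_json(unclass(ledger), file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bind_rows(tests, .id = "contrast"),
                       file.path(out_dir, "tests.json"), digits = NA)
  run_cfg <- list(
    simulated = is.null(in_dir), seed = if (is.null(in_dir)) seed else NULL,
    n_reports = if (is.null(in_dir)) config$n_reports else nrow(rs$reports),
    min_causality = min_causality, criteria = unclass(criteria),
    top_n = top_n)
  jsonlite::write_json(run_cfg, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "ledger.json", "tests.json", "run_config.json")
  if (is.null(in_dir)) {
    files <- c("reports.csv", "drugs.csv", "adrs.csv", "dictionary.csv",
               "ground_truth.json", files)
  }
  manifest <- tibble(
    file = files,
    rows = purrr::map_int(files, function(f) {
      p <- file.path(out_dir, f)
      if (grepl("\\.csv$", f)) {
        length(readr::read_lines(p, progress = FALSE)) - 1L
      } else {
        NA_integer_
      }
    })
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"),
                   progress = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  invisible(list(pairs = pairs, ledger = ledger,
                 characteristics = characteristics, soc = socs,
                 top_scb = top_scb, top_nonscb = top_non, sexrep = sexrep,
                 screen_pt = screen_pt, screen_soc = screen_soc,
                 onset = onset, tests = tests, manifest = manifest,
                 out_dir = out_dir))
}

# fixed-width markdown-ish rendering helpers ---------------------------------

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "-", formatC(round_half_up(x, digits), format = "f",
                                digits = digits, big.mark = ","))
}

md_table <- function(df) {
  df[] <- lapply(df, as.character)
  df[is.na(df)] <- "-"
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Render a frequency table for display
#'
#' Markdown table with counts and 1-decimal percentages (rounded half up,
#' display only).
#'
#' @param x a `frequency_table`.
#' @return a character scalar of markdown.
#' @export
render_characteristics <- function(x) {
  df <- tibble(
    Characteristic = x$characteristic, Category = x$category,
    `N total` = fmt_num(x$n_total, 0), `% total` = fmt_num(x$pct_total, 1),
    `N SCB` = fmt_num(x$n_scb, 0), `% SCB` = fmt_num(x$pct_scb, 1),
    `N non-SCB` = fmt_num(x$n_nonscb, 0),
    `% non-SCB` = fmt_num(x$pct_nonscb, 1))
  md_table(df)
}

#' Render a signal screen as an ROR grid
#'
#' One row per (drug, event) with `ROR (low-high)` at 2 decimals and an
#' annotation: `>1` (interval above 1), `<1` (below 1), `ns` (interval
#' straddles 1 or inestimable).
#'
#' @param x a `signal_screen`.
#' @return a character scalar of markdown.
#' @export
render_signal_grid <- function(x) {
  annot <- ifelse(!x$estimable, "ns",
           ifelse(x$ror_low > 1, ">1",
           ifelse(x$ror_high < 1, "<1", "ns")))
  df <- tibble(
    Drug = x$drug, Event = x$event_name, N = fmt_num(x$n, 0),
    `ROR (95% CI)` = sprintf("%s (%s-%s)", fmt_num(x$ror, 2),
                             fmt_num(x$ror_low, 2), fmt_num(x$ror_high, 2)),
    Direction = annot, Signal = ifelse(x$signal, "yes", ""))
  md_table(df)
}

#' Render an onset comparison table
#'
#' @param x an `onset_comparison`.
#' @return a character scalar of markdown.
#' @export
render_onset <- function(x) {
  tri <- function(m, q1, q3) {
    ifelse(is.na(m), "-", sprintf("%s (%s, %s)", fmt_num(m, 0),
                                  fmt_num(q1, 0), fmt_num(q3, 0)))
  }
  df <- tibble(
    ADR = x$pt_name, Mode = x$mode,
    `SCBs` = tri(x$median_scb, x$q1_scb, x$q3_scb),
    `Non-SCBs` = tri(x$median_nonscb, x$q1_nonscb, x$q3_nonscb),
    `Median diff` = fmt_num(x$median_diff, 0))
  md_table(df)
}

#' Render every table of a pipeline output directory
#'
#' Reads the artifacts written by [run_pipeline()] and assembles a single
#' human-readable markdown report (characteristics, SOC distribution, top
#' reactions, signal grid, onset comparison).
#'
#' @param dir a directory produced by [run_pipeline()].
#' @param file optional path to also write the report to.
#' @return the report as a character scalar, invisibly when `file` is given.
#' @export
render_tables <- function(dir, file = NULL) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      abort_asm(sprintf("missing artifact: %s", p), class = "asm_io_error")
    }
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  chars <- need("characteristics.csv")
  socs <- need("soc_distribution.csv")
  top_scb <- need("top_adrs_scb.csv")
  top_non <- need("top_adrs_nonscb.csv")
  sig <- need("signals_soc.csv")
  onset <- need("onset.csv")
  sections <- c(
    "# Analysis report", "",
    "## Characteristics of reporting", render_characteristics(chars), "",
    "## Distribution of pairs by System Organ Class",
    render_characteristics(socs), "",
    "## Top reported reactions (SCBs)",
    md_table(tibble(Rank = fmt_num(top_scb$rank, 0), ADR = top_scb$pt_name,
                    N = fmt_num(top_scb$n, 0),
                    `%` = fmt_num(top_scb$pct, 1))), "",
    "## Top reported reactions (non-SCBs)",
    md_table(tibble(Rank = fmt_num(top_non$rank, 0), ADR = top_non$pt_name,
                    N = fmt_num(top_non$n, 0),
                    `%` = fmt_num(top_non$pct, 1))), "",
    "## Signal screen (SOC level)", render_signal_grid(sig), "",
    "## Onset-time comparison", render_onset(onset), "")
  out <- paste(sections, collapse = "\n")
  if (!is.null(file)) {
    readr::write_lines(out, file)
    return(invisible(out))
  }
  out
}
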