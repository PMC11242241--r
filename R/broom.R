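# tidy()/glance() methods for the package's result objects.

#' @method tidy group_test
#' @export
tidy.group_test <- function(x, ...) {
  tibble(method = x$test, statistic = x$statistic, df = x$df,
         p.value = x$p_value)
}

#' @method glance group_test
#' @export
glance.group_test <- function(x, ...) {
  tibble(method = x$test, statistic = x$statistic, df = x$df,
         p.value = x$p_value, applicable = x$applicable)
}

#' @method tidy signal_screen
#' @export
tidy.signal_screen <- function(x, ...) {
  tibble(drug = x$drug, group = x$group, event = x$event_name,
         event_code = x$event_code, n = x$n,
         estimate = x$ror, conf.low = x$ror_low, conf.high = x$ror_high,
         prr = x$prr, statistic = x$chi2, ic = x$ic, ic025 = x$ic025,
         signal = x$signal, estimable = x$estimable)
}

#' @method glance signal_screen
#' @export
glance.signal_screen <- function(x, ...) {
  tibble(n_pairs = attr(x, "n_pairs") %||% NA_integer_,
         n_combinations = nrow(x),
         n_signals = sum(x$signal, na.rm = TRUE),
         n_inestimable = sum(!x$estimable))
}

#' @method tidy cleaning_ledger
#' @export
tidy.cleaning_ledger <- function(x, ...) {
  tibble(stage = names(unclass(x)),
         n = unlist(unclass(x), use.names = FALSE))
}

#' @method glance cleaning_ledger
#' @export
glance.cleaning_ledger <- function(x, ...) {
  tibble(input_reports = x$input_reports,
         retained_reports = x$retained_reports,
         excluded = x$input_reports - x$retained_reports,
         pairs_generated = x$pairs_generated,
         pairs_after_causality_filter = x$pairs_after_causality_filter)
}

#' @method tidy contingency_2x2
#' @export
tidy.contingency_2x2 <- function(x, ...) {
  tibble(cell = c("a", "b", "c", "d"),
         drug = c(TRUE, TRUE, FALSE, FALSE),
         event = c(TRUE, FALSE, TRUE, FALSE),
         count = c(x$a, x$b, x$c, x$d))
}

#' @method tidy sexrep_analysis
#' @export
tidy.sexrep_analysis <- function(x, ...) {
  as_tibble(x$by_term)
}

#' @method glance sexrep_analysis
#' @export
glance.sexrep_analysis <- function(x, ...) {
  tibble(n_subset = sum(x$subset_counts[c("a", "c")]),
         n_scb = x$subset_counts[["a"]],
         n_nonscb = x$subset_counts[["c"]],
         scb_share_pct = x$share$pct[x$share$group == "SCB"],
         p.value = x$test$p_value)
}
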