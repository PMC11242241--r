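#' Time-to-onset summary
#'
#' Median and quartiles of `onset_days` (adverse-event onset date minus drug
#' start date) for one reaction term and mechanism group.  Pairs with a
#' missing onset interval are excluded.  The `"within_8_weeks"` mode keeps
#' onsets of at most 56 days (8 weeks, boundary included), the sensitivity
#' restriction that targets type-2 allergic-reaction latency; `"unrestricted"`
#' uses all onsets.  Quartiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7); day-0 onsets are valid
#' observations.
#'
#' @param pairs pair universe from [expand_pairs()].
#' @param pt PT code(s) to summarize, or `NULL` for all.
#' @param group `"SCB"`, `"NON_SCB"`, or `NULL` for all pairs.
#' @param mode `"unrestricted"` or `"within_8_weeks"`.
#' @return a one-row tibble with columns `pt`, `group`, `mode`, `n_used`,
#'   `median_days`, `q1_days`, `q3_days` (NA summaries when no usable pair).
#' @export
onset_summary <- function(pairs, pt = NULL, group = NULL,
                          mode = c("unrestricted", "within_8_weeks")) {
  mode <- match.arg(mode)
  x <- pairs
  if (!is.null(pt)) x <- filter(x, .data$pt_code %in% as.integer(pt))
  if (!is.null(group)) x <- filter(x, .data$group %in% !!group)
  days <- x$onset_days[!is.na(x$onset_days)]
  if (mode == "within_8_weeks") days <- days[days <= 56]
  if (length(days) == 0) {
    return(tibble(pt = paste(pt, collapse = "+"),
                  group = paste(group %||% "all", collapse = "+"),
                  mode = mode, n_used = 0L, median_days = NA_real_,
                  q1_days = NA_real_, q3_days = NA_real_))
  }
  q <- unname(quantile(days, c(0.25, 0.5, 0.75), type = 7))
  tibble(pt = paste(pt %||% "all", collapse = "+"),
         group = paste(group %||% "all", collapse = "+"),
         mode = mode, n_used = length(days),
         median_days = q[2], q1_days = q[1], q3_days = q[3])
}

#' Onset-time comparison between mechanism groups
#'
#' For each requested reaction term (by default the 10 most reported terms
#' in the universe) and each restriction mode, summarizes onset days for
#' sodium channel blockers and for other mechanisms side by side and
#' reports the between-group difference of medians (SCB minus non-SCB).
#'
#' @param pairs pair universe from [expand_pairs()].
#' @param pt_codes PT codes to compare; default: top 10 by overall count.
#' @param modes restriction modes to include.
#' @return a tibble of class `onset_comparison` with one row per
#'   (term, mode): `pt_code`, `pt_name`, `mode`, then `n`, `median`, `q1`,
#'   `q3` for each group (`_scb`, `_nonscb` suffixes) and `median_diff`.
#' @export
onset_comparison <- function(pairs, pt_codes = NULL,
                             modes = c("within_8_weeks", "unrestricted")) {
  if (is.null(pt_codes)) {
    pt_codes <- pairs %>%
      count(.data$pt_code, .data$pt_name) %>%
      arrange(desc(.data$n), .data$pt_name) %>%
      head(10) %>%
      pull(.data$pt_code)
  }
  if (length(pt_codes) == 0) {
    abort_asm("pt_codes must be nonempty", class = "asm_validation_error")
  }
  names_lut <- pairs %>% distinct(.data$pt_code, .data$pt_name)
  rows <- purrr::map(pt_codes, function(code) {
    purrr::map(modes, function(md) {
      s <- onset_summary(pairs, pt = code, group = "SCB", mode = md)
      ns <- onset_summary(pairs, pt = code, group = "NON_SCB", mode = md)
      tibble(
        pt_code = as.integer(code),
        pt_name = names_lut$pt_name[match(code, names_lut$pt_code)],
        mode = md,
        n_scb = s$n_used, median_scb = s$median_days,
        q1_scb = s$q1_days, q3_scb = s$q3_days,
        n_nonscb = ns$n_used, median_nonscb = ns$median_days,
        q1_nonscb = ns$q1_days, q3_nonscb = ns$q3_days,
        median_diff = s$median_days - ns$median_days
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  structure(rows, class = c("onset_comparison", class(rows)))
}
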