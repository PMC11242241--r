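#' 2x2 contingency table over an ADR-drug pair universe
#'
#' Cross-classifies every pair in the universe by a drug selector (a drug
#' name or a mechanism group) and an event selector (PT code(s) or SOC
#' code(s)): `a` = target drug and target event, `b` = target drug, other
#' events, `c` = other drugs, target event, `d` = neither.  Each pair is
#' counted exactly once, so `a + b + c + d` equals the size of the universe.
#' The comparator is always "all other pairs in the supplied universe";
#' pre-filter the universe (e.g. to one mechanism group) for within-group
#' contrasts.
#'
#' @param pairs pair universe from [expand_pairs()].
#' @param drug target drug name (exactly one of `drug`/`group`).
#' @param group target mechanism group, `"SCB"` or `"NON_SCB"`.
#' @param pt target PT code(s) (exactly one of `pt`/`soc`).
#' @param soc target SOC code(s); a set selects their union.
#' @return an object of class `contingency_2x2`.
#' @export
make_contingency <- function(pairs, drug = NULL, group = NULL,
                             pt = NULL, soc = NULL) {
  if (nrow(pairs) == 0) {
    abort_asm("pair universe is empty", class = "asm_validation_error")
  }
  if (is.null(drug) == is.null(group)) {
    abort_asm("supply exactly one of `drug` or `group`",
              class = "asm_config_error")
  }
  if (is.null(pt) == is.null(soc)) {
    abort_asm("supply exactly one of `pt` or `soc`",
              class = "asm_config_error")
  }
  in_drug <- if (!is.null(drug)) {
    pairs$drug_name %in% normalize_drug(drug)
  } else {
    pairs$group %in% group
  }
  in_event <- if (!is.null(pt)) {
    pairs$pt_code %in% as.integer(pt)
  } else {
    pairs$soc_code %in% as.integer(soc)
  }
  as_contingency(
    a = sum(in_drug & in_event),
    b = sum(in_drug & !in_event),
    c = sum(!in_drug & in_event),
    d = sum(!in_drug & !in_event),
    drug_label = if (!is.null(drug)) paste(drug, collapse = "+") else group,
    event_label = paste(c(pt, soc), collapse = "+")
  )
}

#' Construct a 2x2 table from its cells
#'
#' Useful for feeding printed marginals directly into the
#' disproportionality operations.
#'
#' @param a,b,c,d nonnegative integer cell counts (`a` = target drug and
#'   target event; see [make_contingency()]).
#' @param drug_label,event_label optional labels.
#' @return an object of class `contingency_2x2`.
#' @export
as_contingency <- function(a, b, c, d, drug_label = "drug",
                           event_label = "event") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(is.na(cells))) {
    abort_asm("cells must be nonnegative counts", class = "asm_validation_error")
  }
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 drug_label = drug_label, event_label = event_label),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> %s x %s\n", x$drug_label, x$event_label))
  print(matrix(c(x$a, x$c, x$b, x$d), 2, 2,
               dimnames = list(c("drug", "other drugs"),
                               c("event", "other events"))))
  invisible(x)
}

# continuity handling shared by ROR and PRR: Haldane-Anscombe +0.5 on all
# four cells, applied when a zero cell occurs ("auto"), always, or never.
corrected_cells <- function(a, b, c, d, correction) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  apply_c <- switch(correction,
                    auto = zero,
                    always = rep(TRUE, length(a)),
                    none = rep(FALSE, length(a)),
                    abort_asm("correction must be auto/always/none",
                              class = "asm_config_error"))
  k <- ifelse(apply_c, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k,
       corrected = apply_c, zero = zero)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d) / (b c)`; the 95 percent interval uses the log-normal
#' (Woolf) method, `exp(ln ROR +- z * sqrt(1/a + 1/b + 1/c + 1/d))`, on the
#' (optionally continuity-corrected) cells.  With `correction = "none"` a
#' zero cell makes the estimate undefined and raises an error.
#'
#' @param a,b,c,d numeric vectors of cell counts, or pass a
#'   `contingency_2x2` as `a`.
#' @param correction `"auto"` (Haldane-Anscombe +0.5 only when a zero cell
#'   occurs), `"always"`, or `"none"`.
#' @param conf_level confidence level (default 0.95).
#' @return a tibble with columns `ror`, `ror_low`, `ror_high`, `corrected`.
#' @export
#' @examples
#' ror_ci(20, 80, 10, 890)
ror_ci <- function(a, b = NULL, c = NULL, d = NULL,
                   correction = c("auto", "always", "none"),
                   conf_level = 0.95) {
  if (inherits(a, "contingency_2x2")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  correction <- match.arg(correction)
  cc <- corrected_cells(a, b, c, d, correction)
  if (correction == "none" && any(cc$zero)) {
    abort_asm("ROR undefined: zero cell with correction disabled",
              class = "asm_undefined_estimate")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  tibble(ror = est,
         ror_low = exp(log(est) - z * se),
         ror_high = exp(log(est) + z * se),
         corrected = cc$corrected)
}

#' Proportional reporting ratio
#'
#' `PRR = (a / (a + b)) / (c / (c + d))`: the proportion of the target event
#' among the target drug's pairs over the same proportion among all other
#' drugs' pairs.  A zero denominator (`a + b = 0`, `c + d = 0`, or `c = 0`)
#' makes the estimate undefined unless the continuity correction applies.
#'
#' @inheritParams ror_ci
#' @return numeric vector of PRR values.
#' @export
#' @examples
#' prr(10, 90, 50, 850)
prr <- function(a, b = NULL, c = NULL, d = NULL,
                correction = c("auto", "always", "none")) {
  if (inherits(a, "contingency_2x2")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  correction <- match.arg(correction)
  cc <- corrected_cells(a, b, c, d, correction)
  undef <- (cc$a + cc$b) == 0 | (cc$c + cc$d) == 0 | cc$c == 0 |
    (correction == "none" & cc$zero)
  if (any(undef)) {
    abort_asm("PRR undefined: zero cell or denominator",
              class = "asm_undefined_estimate")
  }
  (cc$a / (cc$a + cc$b)) / (cc$c / (cc$c + cc$d))
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Pearson chi-square with continuity correction,
#' `sum(max(0, |O - E| - 0.5)^2 / E)` over the four cells - the classic
#' convention accompanying PRR signal criteria.  Any zero marginal makes the
#' statistic 0, with a warning.
#'
#' @param a,b,c,d numeric vectors of cell counts, or a `contingency_2x2`.
#' @param yates apply the continuity correction (default TRUE).
#' @return numeric vector of statistics.
#' @export
chi2_yates <- function(a, b = NULL, c = NULL, d = NULL, yates = TRUE) {
  if (inherits(a, "contingency_2x2")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0 | n == 0
  if (any(degenerate)) {
    warn("chi-square set to 0 for table(s) with a zero marginal")
  }
  out <- numeric(length(a))
  ok <- !degenerate
  if (any(ok)) {
    e <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2)[ok, , drop = FALSE] / n[ok]
    o <- cbind(a, b, c, d)[ok, , drop = FALSE]
    dev <- abs(o - e) - if (yates) 0.5 else 0
    dev[dev < 0] <- 0
    out[ok] <- rowSums(dev^2 / e)
  }
  out
}

#' Information component with its lower 95 percent bound (IC025)
#'
#' The shrunk observed-to-expected information component:
#' `E = (a + b)(a + c) / N`, `IC = log2((a + 0.5) / (E + 0.5))`, with the
#' closed-form approximation to the 2.5th percentile of the posterior,
#' `IC025 = IC - 3.3 (a + 0.5)^{-1/2} - 2 (a + 0.5)^{-3/2}`.  The +0.5
#' shrinkage is built in; no further continuity correction is applied to the
#' raw counts.
#'
#' @param a,b,c,d numeric vectors of cell counts, or a `contingency_2x2`.
#' @return a tibble with columns `ic`, `ic025`.
#' @export
#' @examples
#' information_component(8, 2, 18, 72)
information_component <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_2x2")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  n <- a + b + c + d
  if (any(n == 0) || any(a + b == 0) || any(a + c == 0)) {
    abort_asm("IC requires N > 0 and nonzero drug and event marginals",
              class = "asm_undefined_estimate")
  }
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  tibble(ic = ic, ic025 = ic025)
}

#' Signal criteria
#'
#' Thresholds of the conjunctive signal definition.  Defaults: at least 3
#' cases, ROR >= 2, PRR >= 2, chi-square >= 4, IC025 >= 0.
#'
#' @param min_cases,min_ror,min_prr,min_chi2,min_ic025 thresholds.
#' @return an object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_cases = 3, min_ror = 2, min_prr = 2,
                            min_chi2 = 4, min_ic025 = 0) {
  structure(list(min_cases = min_cases, min_ror = min_ror, min_prr = min_prr,
                 min_chi2 = min_chi2, min_ic025 = min_ic025),
            class = "signal_criteria")
}

#' Apply the conjunctive signal criterion
#'
#' TRUE iff the number of cases, ROR, PRR, chi-square and IC025 all meet
#' their thresholds.  All five gates are conjunctive; no multiple-testing
#' adjustment is applied.
#'
#' @param results a data frame with columns `n`, `ror`, `prr`, `chi2`,
#'   `ic025` (e.g. a row set from [screen_signals()] or
#'   [disproportionality()]).
#' @param criteria a [signal_criteria()].
#' @return logical vector.
#' @export
detect_signal <- function(results, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  results$n >= criteria$min_cases &
    results$ror >= criteria$min_ror &
    results$prr >= criteria$min_prr &
    results$chi2 >= criteria$min_chi2 &
    results$ic025 >= criteria$min_ic025
}

#' All disproportionality statistics for one table
#'
#' @param table a `contingency_2x2`.
#' @param criteria a [signal_criteria()].
#' @param correction continuity rule for ROR and PRR (see [ror_ci()]).
#' @return a one-row tibble with `n`, `ror`, `ror_low`, `ror_high`, `prr`,
#'   `chi2`, `ic`, `ic025`, `signal`, `estimable`.
#' @export
disproportionality <- function(table, criteria = signal_criteria(),
                               correction = "auto") {
  stopifnot(inherits(table, "contingency_2x2"))
  r <- ror_ci(table, correction = correction)
  out <- tibble(
    drug = table$drug_label,
    event = table$event_label,
    n = table$a,
    ror = r$ror, ror_low = r$ror_low, ror_high = r$ror_high,
    prr = prr(table, correction = correction),
    chi2 = suppressWarnings(chi2_yates(table)),
    estimable = !(table$a == 0 || table$b == 0 || table$c == 0 ||
                    table$d == 0)
  )
  ic <- information_component(table)
  out$ic <- ic$ic
  out$ic025 <- ic$ic025
  out$signal <- detect_signal(out, criteria)
  out
}

#' Screen every drug-event combination in a pair universe
#'
#' Builds the 2x2 table of each (drug, event) combination against all other
#' pairs in the universe and computes ROR (with Woolf interval), PRR,
#' Yates-corrected chi-square, IC and IC025, plus the conjunctive signal
#' flag.  Undefined estimates (a zero raw cell) are returned as flagged
#' rows (`estimable = FALSE`, statistics from continuity-corrected cells),
#' never as failures.
#'
#' @param pairs pair universe from [expand_pairs()].
#' @param level `"pt"` (events are preferred terms) or `"soc"` (events are
#'   system organ classes).
#' @param drugs drug names to screen (default: all in the universe).
#' @param events event codes to screen (default: all at the chosen level).
#' @param criteria a [signal_criteria()].
#' @param correction continuity rule for ROR/PRR.
#' @return a tibble of class `signal_screen`, one row per (drug, event),
#'   sorted by drug then descending ROR, with columns `drug`, `group`,
#'   `event_code`, `event_name`, `n`, `ror`, `ror_low`, `ror_high`, `prr`,
#'   `chi2`, `ic`, `ic025`, `signal`, `estimable`.
#' @export
screen_signals <- function(pairs, level = c("pt", "soc"), drugs = NULL,
                           events = NULL, criteria = signal_criteria(),
                           correction = "auto") {
  level <- match.arg(level)
  if (nrow(pairs) == 0) {
    abort_asm("pair universe is empty", class = "asm_validation_error")
  }
  ev_code <- if (level == "pt") pairs$pt_code else pairs$soc_code
  ev_name <- if (level == "pt") pairs$pt_name else pairs$soc_name
  universe <- tibble(drug = pairs$drug_name, group = pairs$group,
                     event_code = ev_code, event_name = ev_name)
  n_tot <- nrow(universe)
  drug_totals <- universe %>% count(.data$drug, .data$group, name = "n_drug")
  event_totals <- universe %>%
    count(.data$event_code, .data$event_name, name = "n_event")
  cells <- universe %>%
    count(.data$drug, .data$group, .data$event_code, .data$event_name,
          name = "a")
  grid <- tidyr::expand_grid(
    drug_totals %>% select("drug", "group", "n_drug"),
    event_totals %>% select("event_code", "event_name", "n_event")
  ) %>%
    left_join(cells,
              by = c("drug", "group", "event_code", "event_name")) %>%
    mutate(a = ifelse(is.na(.data$a), 0L, .data$a))
  if (!is.null(drugs)) {
    grid <- filter(grid, .data$drug %in% normalize_drug(drugs))
  }
  if (!is.null(events)) {
    grid <- filter(grid, .data$event_code %in% as.integer(events))
  }
  a <- grid$a
  b <- grid$n_drug - a
  cc <- grid$n_event - a
  d <- n_tot - grid$n_drug - grid$n_event + a

  r <- ror_ci(a, b, cc, d, correction = correction)
  kc <- corrected_cells(a, b, cc, d, correction)
  prr_v <- (kc$a / (kc$a + kc$b)) / (kc$c / (kc$c + kc$d))
  ic_tbl <- information_component(a, b, cc, d)
  out <- grid %>%
    mutate(
      n = a,
      ror = r$ror, ror_low = r$ror_low, ror_high = r$ror_high,
      prr = prr_v,
      chi2 = suppressWarnings(chi2_yates(a, b, cc, d)),
      ic = ic_tbl$ic, ic025 = ic_tbl$ic025,
      estimable = a > 0 & b > 0 & cc > 0 & d > 0
    ) %>%
    mutate(signal = detect_signal(., criteria)) %>%
    select("drug", "group", "event_code", "event_name", "n", "ror",
           "ror_low", "ror_high", "prr", "chi2", "ic", "ic025", "signal",
           "estimable") %>%
    arrange(.data$drug, desc(.data$ror))
  class(out) <- c("signal_screen", class(out))
  attr(out, "criteria") <- criteria
  attr(out, "n_pairs") <- n_tot
  out
}
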