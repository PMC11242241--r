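# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used when mirroring printed tables (1-decimal percentages,
#' 2-decimal ratios).  Base `round()` rounds half to even; printed
#' pharmacovigilance tables conventionally round half up, so renderers use
#' this helper.  Full precision is always retained in returned tibbles;
#' rounding is display-only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(31.65, 2.5, -2.5), 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by machine epsilon so binary representations of exact halves
  # (0.15 * 10 = 1.4999...) still round up
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# percentage with full precision; renderers round
pct_of <- function(n, denom) {
  out <- 100 * n / denom
  out[!is.finite(out)] <- NA_real_
  out
}

# stop with a classed condition so callers can test error contracts
abort_asm <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "asmsignals_error"), ...)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_asm(
      sprintf("%s is missing mandatory column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "asm_schema_error"
    )
  }
  invisible(df)
}

# drop reader-specific attributes/classes so constructed and re-read tables
# compare equal
canon_tbl <- function(df) {
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df
}

# probability vector check (sums to one within tolerance, nonnegative)
assert_prob <- function(p, what, tol = 1e-9) {
  if (any(p < 0) || any(is.na(p))) {
    abort_asm(sprintf("%s must be nonnegative and non-missing", what),
              class = "asm_config_error")
  }
  if (abs(sum(p) - 1) > tol) {
    abort_asm(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)),
              class = "asm_config_error")
  }
  invisible(p)
}
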