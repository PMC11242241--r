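# ggplot2 displays for the main result types.

#' Forest plot of a signal screen
#'
#' Reporting odds ratios with their 95 percent Woolf intervals on a log
#' scale, one panel per drug, signals highlighted.
#'
#' @param object a `signal_screen` from [screen_signals()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot signal_screen
#' @export
autoplot.signal_screen <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$event_name,
                                   colour = .data$signal)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_low,
                                         xmax = .data$ror_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$drug)) +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "Signal") +
    ggplot2::theme_minimal()
}

#' Dumbbell plot of an onset comparison
#'
#' Median onset days per reaction term for sodium channel blockers versus
#' other mechanisms, one panel per restriction mode.
#'
#' @param object an `onset_comparison` from [onset_comparison()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot onset_comparison
#' @export
autoplot.onset_comparison <- function(object, ...) {
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(c("median_scb", "median_nonscb"),
                        names_to = "group", values_to = "median_days") %>%
    mutate(group = ifelse(.data$group == "median_scb", "SCB", "non-SCB"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_days,
                                   y = .data$pt_name,
                                   colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$pt_name),
                       colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::labs(x = "Median onset (days)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of the SOC distribution by mechanism group
#'
#' @param x a `frequency_table` from [soc_distribution()].
#' @return a ggplot object.
#' @export
plot_soc_distribution <- function(x) {
  df <- as_tibble(x) %>%
    tidyr::pivot_longer(c("pct_scb", "pct_nonscb"), names_to = "group",
                        values_to = "pct") %>%
    mutate(group = ifelse(.data$group == "pct_scb", "SCB", "non-SCB"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct,
                                   y = stats::reorder(.data$category,
                                                      .data$pct),
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "% of group pairs", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
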