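# Frequency tables and SCB vs non-SCB group contrasts.

# count one stratifier by mechanism group, with total/SCB/non-SCB
# percentages; denominators are the column (group) totals, Unknown rows
# included.  Percentages are full precision; round only for display.
freq_block <- function(pairs, var, label) {
  denom_tot <- nrow(pairs)
  denom_scb <- sum(pairs$group == "SCB")
  denom_non <- sum(pairs$group == "NON_SCB")
  v <- pairs[[var]]
  lv <- if (is.factor(v)) levels(v) else sort(unique(v))
  tab <- tibble(category = as.character(v), group = pairs$group) %>%
    count(.data$category, .data$group) %>%
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  for (g in c("SCB", "NON_SCB")) if (!g %in% names(tab)) tab[[g]] <- 0L
  tab %>%
    mutate(characteristic = label,
           n_total = .data$SCB + .data$NON_SCB,
           pct_total = pct_of(.data$n_total, denom_tot),
           n_scb = .data$SCB, pct_scb = pct_of(.data$SCB, denom_scb),
           n_nonscb = .data$NON_SCB,
           pct_nonscb = pct_of(.data$NON_SCB, denom_non)) %>%
    arrange(match(.data$category, lv)) %>%
    select("characteristic", "category", "n_total", "pct_total",
           "n_scb", "pct_scb", "n_nonscb", "pct_nonscb")
}

#' Characteristics-of-reporting table
#'
#' Stratified frequency table over the ADR-drug pair universe: sex, age
#' group, original reporter, causality assessment, seriousness, and
#' seriousness categories, each counted for the total and per mechanism
#' group.  Denominators are the group pair totals (Unknown rows included,
#' so percentages within a stratifier sum to 100); seriousness-category
#' rows can overlap when a report carries several categories, mirroring the
#' usual presentation.
#'
#' @param pairs pair universe from [expand_pairs()].
#' @return a tibble of class `frequency_table` with columns
#'   `characteristic`, `category`, `n_total`, `pct_total`, `n_scb`,
#'   `pct_scb`, `n_nonscb`, `pct_nonscb`.
#' @export
characteristics_table <- function(pairs) {
  pairs <- mutate(pairs,
                  seriousness = ifelse(.data$serious, "Yes", "No"))
  blocks <- bind_rows(
    freq_block(pairs, "sex", "Sex"),
    freq_block(pairs, "age_group", "Age group"),
    freq_block(pairs, "reporter", "Original reporter"),
    freq_block(mutate(pairs,
                      causality = factor(.data$causality,
                                         levels = rev(causality_levels()))),
               "causality", "Assessment"),
    freq_block(mutate(pairs,
                      seriousness = factor(.data$seriousness,
                                           levels = c("Yes", "No"))),
               "seriousness", "Seriousness")
  )
  cats <- pairs %>%
    filter(.data$serious, .data$serious_categories != "") %>%
    tidyr::separate_rows("serious_categories", sep = ";") %>%
    rename(category_value = "serious_categories")
  if (nrow(cats) > 0) {
    cat_block <- freq_block(
      mutate(cats, category_value = factor(.data$category_value,
                                           levels = seriousness_categories())),
      "category_value", "Seriousness category")
    # denominators for category rows are still the full group totals
    denom <- c(nrow(pairs), sum(pairs$group == "SCB"),
               sum(pairs$group == "NON_SCB"))
    cat_block <- cat_block %>%
      mutate(pct_total = pct_of(.data$n_total, denom[1]),
             pct_scb = pct_of(.data$n_scb, denom[2]),
             pct_nonscb = pct_of(.data$n_nonscb, denom[3]))
    blocks <- bind_rows(blocks, cat_block)
  }
  structure(blocks, class = c("frequency_table", class(blocks)))
}

#' Distribution of pairs across System Organ Classes
#'
#' One row per SOC, sorted by total count descending, with per-group counts
#' and percentages (denominators are the group pair totals).
#'
#' @param pairs pair universe from [expand_pairs()].
#' @return a tibble of class `frequency_table`.
#' @export
soc_distribution <- function(pairs) {
  out <- pairs %>%
    mutate(category = .data$soc_name) %>%
    freq_block("category", "SOC") %>%
    arrange(desc(.data$n_total))
  soc_codes <- pairs %>%
    distinct(.data$soc_name, .data$soc_code)
  out <- out %>%
    left_join(soc_codes, by = c("category" = "soc_name")) %>%
    select("characteristic", "category", "soc_code", everything())
  structure(out, class = c("frequency_table", class(out)))
}

#' Most frequently reported adverse reactions
#'
#' Ranks preferred terms by report count within one mechanism group (or the
#' whole universe), descending, ties broken alphabetically by PT name for
#' deterministic output.  Percentages use the group total as denominator; a
#' final `"Others"` remainder row accounts for everything outside the top
#' `n`.  If `n` exceeds the number of distinct terms the full list is
#' returned without padding.
#'
#' @param pairs pair universe from [expand_pairs()].
#' @param group `"SCB"`, `"NON_SCB"`, or `NULL` for all pairs.
#' @param n number of top terms (default 20).
#' @return a tibble with columns `rank`, `pt_code`, `pt_name`, `n`, `pct`.
#' @export
top_adrs <- function(pairs, group = NULL, n = 20) {
  stopifnot(n >= 1)
  if (!is.null(group)) pairs <- filter(pairs, .data$group %in% !!group)
  denom <- nrow(pairs)
  counts <- pairs %>%
    count(.data$pt_code, .data$pt_name, name = "n_pt") %>%
    arrange(desc(.data$n_pt), .data$pt_name) %>%
    mutate(rank = row_number())
  top <- head(counts, n)
  out <- top %>%
    mutate(pct = pct_of(.data$n_pt, denom)) %>%
    select("rank", "pt_code", "pt_name", n = "n_pt", "pct")
  rest <- denom - sum(out$n)
  if (nrow(counts) > nrow(top)) {
    out <- bind_rows(out, tibble(rank = NA_integer_, pt_code = NA_integer_,
                                 pt_name = "Others", n = rest,
                                 pct = pct_of(rest, denom)))
  }
  out
}

#' Compare a categorical stratifier between mechanism groups
#'
#' Builds the category x group contingency table and tests homogeneity:
#' Fisher's exact test when the table is 2x2 and any expected cell is below
#' 5, otherwise the chi-square test (with Yates continuity correction on
#' 2x2 tables, the `stats::chisq.test()` default).  Two-sided Fisher
#' p-values sum the probabilities of all tables no more probable than the
#' observed one (the conventional definition).
#'
#' @param pairs pair universe from [expand_pairs()].
#' @param stratifier name of a categorical column of `pairs`.
#' @return an object of class `group_test` with fields `test`, `statistic`,
#'   `df`, `p_value`, `table`, `applicable`.
#' @export
compare_groups <- function(pairs, stratifier) {
  if (!stratifier %in% names(pairs)) {
    abort_asm(sprintf("no column `%s` in pairs", stratifier),
              class = "asm_schema_error")
  }
  if (length(unique(pairs$group)) < 2) {
    abort_asm("both mechanism groups must be present",
              class = "asm_validation_error")
  }
  tab <- table(as.character(pairs[[stratifier]]), pairs$group)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) {
    return(structure(list(test = NA_character_, statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_, table = tab,
                          applicable = FALSE),
                     class = "group_test"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected < 5)) {
    ft <- fisher.test(tab)
    res <- list(test = "fisher_exact", statistic = NA_real_, df = NA_real_,
                p_value = ft$p.value, table = tab, applicable = TRUE)
  } else {
    ct <- suppressWarnings(chisq.test(tab))
    res <- list(test = "chi_square", statistic = unname(ct$statistic),
                df = unname(ct$parameter), p_value = ct$p.value, table = tab,
                applicable = TRUE)
  }
  structure(res, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  if (!x$applicable) {
    cat("<group_test> not applicable (degenerate table)\n")
  } else {
    cat(sprintf("<group_test> %s: statistic = %s, p = %.4g\n", x$test,
                ifelse(is.na(x$statistic), "-",
                       formatC(x$statistic, digits = 4, format = "g")),
                x$p_value))
  }
  invisible(x)
}

#' Sexual/reproductive adverse-reaction analysis
#'
#' Restricts the universe to pairs whose SOC belongs to the
#' sexual/reproductive set (default codes 1410, 1420, 1500, 1600), tabulates
#' per-SOC and per-PT counts by mechanism group, and tests whether subset
#' membership differs between groups with a two-sided Fisher's exact test on
#' the 2x2 (SCB-and-subset, SCB-and-rest, non-SCB-and-subset,
#' non-SCB-and-rest) over the full universe.
#'
#' @param pairs pair universe from [expand_pairs()].
#' @param soc_set SOC codes defining the subset
#'   (default [sexual_reproductive_socs()]).
#' @return an object of class `sexrep_analysis`: a list with `by_term`
#'   (counts per SOC/PT by group), `subset_counts` (the 2x2 cells), `share`
#'   (percentage split of subset pairs between groups), and `test` (a
#'   `group_test` holding the Fisher result; not applicable when the subset
#'   is empty).
#' @export
sexual_reproductive_analysis <- function(pairs,
                                         soc_set = sexual_reproductive_socs()) {
  soc_set <- sexual_reproductive_socs(soc_set)
  in_sub <- pairs$soc_code %in% soc_set
  sub <- pairs[in_sub, ]
  by_term <- sub %>%
    count(.data$soc_code, .data$soc_name, .data$pt_code, .data$pt_name,
          .data$group) %>%
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L) %>%
    arrange(.data$soc_code, .data$pt_name)
  for (g in c("SCB", "NON_SCB")) if (!g %in% names(by_term)) by_term[[g]] <- 0L
  a <- sum(in_sub & pairs$group == "SCB")
  b <- sum(!in_sub & pairs$group == "SCB")
  c <- sum(in_sub & pairs$group == "NON_SCB")
  d <- sum(!in_sub & pairs$group == "NON_SCB")
  n_sub <- a + c
  share <- tibble(group = c("SCB", "NON_SCB"), n = c(a, c),
                  pct = pct_of(c(a, c), n_sub))
  if (n_sub == 0) {
    test <- structure(list(test = NA_character_, statistic = NA_real_,
                           df = NA_real_, p_value = NA_real_,
                           table = matrix(c(a, c, b, d), 2), applicable = FALSE),
                      class = "group_test")
  } else {
    ft <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
    test <- structure(list(test = "fisher_exact", statistic = NA_real_,
                           df = NA_real_, p_value = ft$p.value,
                           table = matrix(c(a, b, c, d), nrow = 2,
                                          byrow = TRUE,
                                          dimnames = list(c("SCB", "NON_SCB"),
                                                          c("subset", "rest"))),
                           applicable = TRUE),
                      class = "group_test")
  }
  structure(list(by_term = by_term,
                 subset_counts = c(a = a, b = b, c = c, d = d),
                 share = share, test = test),
            class = "sexrep_analysis")
}

#' @export
print.sexrep_analysis <- function(x, ...) {
  cat(sprintf(
    "<sexrep_analysis> %d subset pairs (SCB %d, non-SCB %d); Fisher p = %s\n",
    sum(x$subset_counts[c("a", "c")]), x$subset_counts[["a"]],
    x$subset_counts[["c"]],
    ifelse(x$test$applicable, formatC(x$test$p_value, format = "g"), "-")))
  invisible(x)
}
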