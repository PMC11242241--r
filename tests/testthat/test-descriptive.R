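test_that("characteristics percentages use group totals as denominators", {
  pairs <- random_pair_universe(n = 10, seed = 17)
  pairs$sex <- c(rep("female", 6), rep("male", 4))
  ft <- characteristics_table(pairs)
  fem <- ft[ft$characteristic == "Sex" & ft$category == "female", ]
  expect_equal(fem$n_total, 6)
  expect_equal(fem$pct_total, 60)
})

test_that("group shares reproduce printed marginal arithmetic", {
  # 14,847 SCB of 46,963 pairs -> 31.6% at 1-decimal display rounding
  pairs <- marginal_pair_universe(14847, 32116)
  ft <- characteristics_table(pairs)
  sex_total <- sum(ft$n_total[ft$characteristic == "Sex"])
  expect_equal(sex_total, 46963)
  expect_equal(round_half_up(100 * 14847 / 46963, 1), 31.6)
  expect_equal(round_half_up(100 * 32116 / 46963, 1), 68.4)
})

test_that("frequency tables conserve their denominators", {
  pairs <- random_pair_universe(n = 137, seed = 23)
  ft <- characteristics_table(pairs)
  for (block in c("Sex", "Age group", "Original reporter", "Assessment",
                  "Seriousness")) {
    rows <- ft[ft$characteristic == block, ]
    expect_equal(sum(rows$n_total), nrow(pairs))
    expect_equal(sum(rows$n_scb), sum(pairs$group == "SCB"))
    expect_equal(sum(rows$pct_total), 100, tolerance = 1e-9)
  }
})

test_that("SOC distribution sorts by total and matches a grouped count", {
  pairs <- random_pair_universe(n = 211, seed = 5)
  sd <- soc_distribution(pairs)
  expect_true(all(diff(sd$n_total) <= 0))
  want <- table(pairs$soc_name)
  expect_equal(sum(sd$n_total), nrow(pairs))
  for (i in seq_len(nrow(sd))) {
    expect_equal(sd$n_total[i], unname(want[sd$category[i]]),
                 ignore_attr = TRUE)
  }
  # single-SOC universe: one row at 100%
  uni <- dplyr::mutate(pairs, soc_code = 100L, soc_name = "Skin")
  sd1 <- soc_distribution(uni)
  expect_equal(nrow(sd1), 1)
  expect_equal(sd1$pct_total, 100)
})

test_that("top reactions rank by count with alphabetical tie-break and Others row", {
  pairs <- random_pair_universe(n = 60, seed = 8)
  pairs$pt_name <- rep(c("Rash", "Nausea", "Dizziness"), each = 20)
  pairs$pt_code <- rep(c(10001L, 60001L, 41001L), each = 20)
  top <- top_adrs(pairs, n = 2)
  # counts tie at 20 -> alphabetical: Dizziness, Nausea
  expect_equal(top$pt_name, c("Dizziness", "Nausea", "Others"))
  expect_equal(top$n, c(20L, 20L, 20L))
  # n exceeding distinct PT count returns the full list, no padding
  full <- top_adrs(pairs, n = 50)
  expect_equal(nrow(full), 3)
  expect_equal(sum(full$n), nrow(pairs))
  expect_equal(sum(full$pct), 100, tolerance = 1e-9)
})

test_that("top-reaction percentages reproduce the printed share", {
  # rash 2,644 of 14,847 SCB pairs -> 17.8%
  d <- default_term_dictionary()
  pairs <- marginal_pair_universe(14847, 0, scb_subset = 2644,
                                  subset_soc = 1420L)
  pairs$pt_code[1:2644] <- d$pt_code[d$pt_name == "Rash"]
  pairs$pt_name[1:2644] <- "Rash"
  top <- top_adrs(pairs, group = "SCB", n = 10)
  rash <- top[top$pt_name == "Rash", ]
  expect_equal(rash$n, 2644L)
  expect_equal(round_half_up(rash$pct, 1), 17.8)
})

test_that("group contrasts pick the right test and match textbook arithmetic", {
  pairs <- random_pair_universe(n = 80, seed = 2)
  # identical distributions in both groups -> statistic 0, p = 1
  base <- dplyr::bind_rows(
    dplyr::mutate(pairs[1:40, ], group = "SCB", sex = rep(c("male", "female"),
                                                          20)),
    dplyr::mutate(pairs[1:40, ], group = "NON_SCB",
                  sex = rep(c("male", "female"), 20)))
  gt0 <- compare_groups(base, "sex")
  expect_equal(gt0$statistic, 0)
  expect_equal(gt0$p_value, 1)
  # symmetric sparse 2x2 goes through Fisher with p = 1
  sym <- dplyr::bind_rows(
    dplyr::mutate(pairs[1:8, ], group = "SCB",
                  sex = rep(c("male", "female"), each = 4)),
    dplyr::mutate(pairs[1:8, ], group = "NON_SCB",
                  sex = rep(c("male", "female"), each = 4)))
  gts <- compare_groups(sym, "sex")
  expect_equal(gts$test, "fisher_exact")
  expect_equal(gts$p_value, 1)
  # r x c tables match the independently coded Pearson statistic
  withr::with_seed(77, {
    for (i in 1:20) {
      p2 <- random_pair_universe(n = 120, seed = 1000 + i)
      p2$age_group <- sample(c("00-09", "10-19", "20-29"), 120, TRUE)
      gt <- compare_groups(p2, "age_group")
      tab <- table(p2$age_group, p2$group)
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      pearson <- sum((tab - e)^2 / e)
      expect_equal(gt$statistic, pearson, tolerance = 1e-9)
    }
  })
})

test_that("degenerate single-category contrasts are not applicable", {
  pairs <- random_pair_universe(n = 30, seed = 4)
  pairs$sex <- "female"
  gt <- compare_groups(pairs, "sex")
  expect_false(gt$applicable)
  expect_true(is.na(gt$p_value))
})

test_that("sexual/reproductive subset analysis reproduces the headline test", {
  pairs <- marginal_pair_universe(14847, 32116, scb_subset = 64,
                                  nonscb_subset = 43)
  sr <- sexual_reproductive_analysis(pairs)
  expect_equal(unname(sr$subset_counts), c(64, 14783, 43, 32073))
  expect_equal(sr$share$pct[sr$share$group == "SCB"], 100 * 64 / 107)
  expect_equal(round_half_up(sr$share$pct, 1), c(59.8, 40.2))
  expect_lt(sr$test$p_value, 0.0001)
  # two-sided Fisher agrees with R's implementation
  expect_equal(sr$test$p_value,
               fisher.test(matrix(c(64, 14783, 43, 32073), 2,
                                  byrow = TRUE))$p.value)
})

test_that("subset analysis counts a small fixture by hand", {
  pairs <- marginal_pair_universe(7, 5, scb_subset = 2, nonscb_subset = 1)
  sr <- sexual_reproductive_analysis(pairs)
  expect_equal(unname(sr$subset_counts), c(2, 5, 1, 4))
  expect_equal(sum(sr$by_term$SCB), 2)
  expect_equal(sum(sr$by_term$NON_SCB), 1)
  # Fisher two-sided matches hypergeometric enumeration
  expect_equal(sr$test$p_value, oracle_fisher_p(2, 5, 1, 4),
               tolerance = 1e-12)
  # empty subset: zero rows, test not applicable
  none <- sexual_reproductive_analysis(marginal_pair_universe(5, 5))
  expect_equal(nrow(none$by_term), 0)
  expect_false(none$test$applicable)
})

test_that("Fisher's exact is invariant to simultaneous row and column swaps", {
  withr::with_seed(55, {
    for (i in 1:25) {
      cells <- sample(0:12, 4, replace = TRUE) + c(1, 1, 1, 1)
      p1 <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
      p2 <- fisher.test(matrix(cells[c(4, 3, 2, 1)], 2, byrow = TRUE))$p.value
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  })
})
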