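test_that("contingency construction counts every pair exactly once", {
  pairs <- random_pair_universe(n = 150, seed = 3)
  t1 <- make_contingency(pairs, drug = "valproate",
                         pt = pairs$pt_code[1])
  expect_equal(t1$a + t1$b + t1$c + t1$d, nrow(pairs))
  # degenerate: every pair matches both selectors
  uni <- dplyr::mutate(pairs, drug_name = "valproate", group = "SCB",
                       pt_code = 10001L, soc_code = 100L)
  td <- make_contingency(uni, drug = "valproate", pt = 10001L)
  expect_equal(c(td$a, td$b, td$c, td$d), c(150, 0, 0, 0))
  expect_error(make_contingency(pairs[0, ], drug = "x", pt = 1),
               class = "asm_validation_error")
  expect_error(make_contingency(pairs, drug = "x", group = "SCB", pt = 1),
               class = "asm_config_error")
})

test_that("group x SOC-set marginals reproduce the printed 2x2", {
  # SCB group vs sexual/reproductive SOC set, universe rebuilt from the
  # printed marginals: 64 of 14,847 SCB and 43 of 32,116 non-SCB pairs
  pairs <- marginal_pair_universe(14847, 32116, scb_subset = 64,
                                  nonscb_subset = 43)
  t <- make_contingency(pairs, group = "SCB",
                        soc = sexual_reproductive_socs())
  expect_equal(c(t$a, t$b, t$c, t$d), c(64, 14783, 43, 32073))
  # chi-square far above the signal threshold, and equal to the
  # independently computed textbook statistic
  x2 <- chi2_yates(t)
  expect_gt(x2, 4)
  expect_equal(x2, oracle_chi2_yates(64, 14783, 43, 32073), tolerance = 1e-12)
})

test_that("contingency cells equal nested-loop brute force on random universes", {
  for (seed in c(10, 11, 12)) {
    pairs <- random_pair_universe(n = 80, seed = seed)
    drug <- pairs$drug_name[1]
    pt <- pairs$pt_code[2]
    t <- make_contingency(pairs, drug = drug, pt = pt)
    bf <- brute_force_cells(pairs, drug, pt, level = "pt")
    expect_equal(c(t$a, t$b, t$c, t$d), unname(bf))
    soc <- unique(pairs$soc_code)[1:2]
    grp_drugs <- asm_catalog()$drug_name[asm_catalog()$group == "SCB"]
    t2 <- make_contingency(pairs, group = "SCB", soc = soc)
    bf2 <- brute_force_cells(pairs, grp_drugs, soc, level = "soc")
    expect_equal(c(t2$a, t2$b, t2$c, t2$d), unname(bf2))
  }
})

test_that("ROR point estimate and Woolf interval match direct arithmetic", {
  r0 <- ror_ci(10, 10, 10, 10)
  expect_equal(r0$ror, 1)
  expect_equal(log(r0$ror_high), -log(r0$ror_low))   # symmetric on log scale
  r <- ror_ci(20, 80, 10, 890)
  expect_equal(r$ror, 22.25)
  expect_equal(c(r$ror_low, r$ror_high), oracle_ror_ci(20, 80, 10, 890),
               tolerance = 1e-12)
  expect_false(r$corrected)
})

test_that("zero cells: error without correction, Haldane-Anscombe with", {
  expect_error(ror_ci(5, 0, 3, 7, correction = "none"),
               class = "asm_undefined_estimate")
  r <- ror_ci(5, 0, 3, 7, correction = "auto")
  expect_equal(r$ror, (5.5 * 7.5) / (0.5 * 3.5))
  expect_true(r$corrected)
  expect_error(prr(0, 10, 5, 85, correction = "none"),
               class = "asm_undefined_estimate")
  expect_equal(prr(0, 10, 5, 85, correction = "auto"),
               (0.5 / 11) / (5.5 / 91))
})

test_that("PRR matches direct arithmetic and is 1 on proportional tables", {
  expect_equal(prr(10, 90, 50, 850), 1.8)
  expect_equal(prr(10, 90, 20, 180), 1)
})

test_that("Yates chi-square agrees with the R implementation to 1e-9", {
  withr::with_seed(99, {
    for (i in 1:300) {
      cells <- sample(1:60, 4, replace = TRUE)
      ours <- chi2_yates(cells[1], cells[2], cells[3], cells[4])
      ref <- suppressWarnings(
        chisq.test(matrix(cells, 2, byrow = TRUE), correct = TRUE))
      expect_equal(ours, unname(ref$statistic), tolerance = 1e-9)
    }
  })
  # exactly proportional table: observed equals expected everywhere
  expect_equal(chi2_yates(10, 90, 20, 180), 0)
  expect_warning(z <- chi2_yates(0, 0, 5, 5), "zero marginal")
  expect_equal(z, 0)
})

test_that("information component matches its closed form", {
  # observed equals expected: N=100, margins 10 and 10, a=1 => E=1, IC=0
  ic0 <- information_component(1, 9, 9, 81)
  expect_equal(ic0$ic, 0)
  # a=8, E=2 (margins 10 and 20 over N=100)
  ic1 <- information_component(8, 2, 12, 78)
  expect_equal(ic1$ic, log2(8.5 / 2.5))
  expect_equal(ic1$ic025,
               log2(8.5 / 2.5) - 3.3 / sqrt(8.5) - 2 / 8.5^1.5)
  # the credibility penalty is strictly positive for any count
  withr::with_seed(5, {
    cells <- matrix(sample(0:40, 400, replace = TRUE), ncol = 4) + c(0, 1, 1, 1)
    ics <- information_component(cells[, 1], cells[, 2], cells[, 3],
                                 cells[, 4])
    expect_true(all(ics$ic025 < ics$ic))
  })
})

test_that("IC is zero at a = E and increases in a with margins fixed", {
  # hold N, drug margin (a+b) and event margin (a+c) fixed, vary a
  n <- 1000; rd <- 100; ce <- 50
  a <- 1:49
  ic <- information_component(a, rd - a, ce - a, n - rd - ce + a)$ic
  expect_true(all(diff(ic) > 0))
  e <- rd * ce / n  # = 5
  expect_equal(information_component(5, 95, 45, 855)$ic, 0)
})

test_that("complementing the drug selector inverts the ROR", {
  pairs <- random_pair_universe(n = 300, seed = 21)
  t <- make_contingency(pairs, group = "SCB", pt = pairs$pt_code[1])
  t_c <- make_contingency(pairs, group = "NON_SCB", pt = pairs$pt_code[1])
  expect_equal(c(t_c$a, t_c$b, t_c$c, t_c$d), c(t$c, t$d, t$a, t$b))
  if (t$a > 0 && t$b > 0 && t$c > 0 && t$d > 0) {
    expect_equal(ror_ci(t_c)$ror, 1 / ror_ci(t)$ror)
  }
})

test_that("the signal flag requires all five gates simultaneously", {
  pass <- tibble::tibble(n = 5, ror = 2.5, prr = 2.2, chi2 = 6.1, ic025 = 0.3)
  expect_true(detect_signal(pass))
  expect_false(detect_signal(dplyr::mutate(pass, n = 2)))
  expect_false(detect_signal(dplyr::mutate(pass, chi2 = 3.9)))
  # thresholds are configurable
  expect_true(detect_signal(dplyr::mutate(pass, n = 2),
                            signal_criteria(min_cases = 2)))
})

test_that("screening matches per-table statistics and brute-force counts", {
  pairs <- random_pair_universe(n = 400, seed = 31)
  sc <- screen_signals(pairs, level = "pt")
  expect_equal(sum(sc$n), nrow(pairs))  # cells partition the universe
  for (i in sample.int(nrow(sc), 8)) {
    bf <- brute_force_cells(pairs, sc$drug[i], sc$event_code[i], level = "pt")
    expect_equal(sc$n[i], unname(bf["a"]))
    if (all(bf > 0)) {
      expect_equal(sc$ror[i], oracle_ror(bf[1], bf[2], bf[3], bf[4]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(sc$prr[i], oracle_prr(bf[1], bf[2], bf[3], bf[4]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(sc$chi2[i],
                   oracle_chi2_yates(bf[1], bf[2], bf[3], bf[4]),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(sc$ic025[i],
                   unname(oracle_ic(bf[1], bf[2], bf[3], bf[4])["ic025"]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # sorted by drug then descending ROR within drug
  expect_true(!is.unsorted(sc$drug))
  expect_true(all(unlist(tapply(sc$ror, sc$drug,
                                function(x) diff(x) <= 1e-12))))
})

test_that("degenerate screens are flagged, not fatal", {
  one <- random_pair_universe(n = 1, seed = 7)
  sc <- screen_signals(one, level = "pt")
  expect_equal(nrow(sc), 1)
  expect_false(sc$estimable)
  expect_error(screen_signals(one[0, ]), class = "asm_validation_error")
})

test_that("single-table summary combines all statistics coherently", {
  pairs <- random_pair_universe(n = 500, seed = 13)
  t <- make_contingency(pairs, drug = "valproate", pt = pairs$pt_code[1])
  row <- disproportionality(t)
  expect_true(row$ror_low <= row$ror & row$ror <= row$ror_high)
  expect_lte(row$ic025, row$ic)
  expect_type(row$signal, "logical")
})
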