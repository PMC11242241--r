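test_that("the exclusion cascade counts each report once, at its first failing stage", {
  rs <- make_cascade_fixture()
  out <- clean_reports(rs)
  l <- out$ledger
  expect_equal(l$input_reports, 12L)
  expect_equal(l$excluded_incomplete, 2L)        # C01 (also AE-less), C02
  expect_equal(l$excluded_not_suspected, 2L)     # C03 concomitant, C04 aspirin
  expect_equal(l$excluded_logical_error, 2L)     # C05 onset<start, C06 report<start
  expect_equal(l$excluded_missing_ae, 2L)        # C07, C08
  expect_equal(l$retained_reports, 4L)
  expect_setequal(out$reports$reports$report_id, sprintf("C%02d", 9:12))
})

test_that("ledger conserves reports and rejects impossible accounting", {
  rs <- make_cascade_fixture()
  l <- clean_reports(rs)$ledger
  excluded <- l$excluded_incomplete + l$excluded_not_suspected +
    l$excluded_logical_error + l$excluded_missing_ae
  expect_equal(l$input_reports, l$retained_reports + excluded)
  expect_error(
    cleaning_ledger(10, 1, 1, 1, 1, 5),
    class = "asm_integrity_error")
  expect_error(
    cleaning_ledger(10, 1, 1, 1, 1, 6, pairs_generated = 5,
                    pairs_after_causality_filter = 7),
    class = "asm_integrity_error")
})

test_that("expansion is the cross-product of suspected study drugs and ADRs", {
  d <- default_term_dictionary()
  reports <- tibble::tibble(
    report_id = c("X1", "X2"), sex = "female", age_years = 30,
    reporter = "nurse", serious = FALSE, serious_categories = "",
    report_date = as.Date("2020-06-01"))
  drugs <- tibble::tibble(
    report_id = c("X1", "X1", "X1", "X2"),
    drug_name = c("valproate", "lamotrigine", "aspirin", "ibuprofen"),
    role = c("suspected", "suspected", "suspected", "suspected"),
    start_date = as.Date("2020-05-01"))
  adrs <- tibble::tibble(
    report_id = c("X1", "X1", "X1", "X2"),
    pt_code = d$pt_code[1:4],
    onset_date = as.Date("2020-05-02") + 0:3,
    causality = "possible")
  pairs <- expand_pairs(report_set(reports, drugs, adrs))
  # 2 suspected study drugs x 3 ADRs = 6; non-study-only report contributes 0
  expect_equal(nrow(pairs), 6)
  expect_setequal(unique(pairs$drug_name), c("valproate", "lamotrigine"))
  expect_equal(sum(pairs$report_id == "X2"), 0)
  expect_equal(pairs$onset_days[pairs$pt_code == d$pt_code[1]], c(1L, 1L))
})

test_that("expansion equals brute-force nested-loop enumeration", {
  rs <- make_fixture_reports()
  cat_ <- asm_catalog()
  pairs <- expand_pairs(rs)
  # naive oracle: loop over reports, suspected study drugs, resolvable ADRs
  want <- 0L
  for (rid in rs$reports$report_id) {
    dr <- rs$drugs[rs$drugs$report_id == rid &
                     rs$drugs$role == "suspected" &
                     rs$drugs$drug_name %in% cat_$drug_name, ]
    ad <- rs$adrs[rs$adrs$report_id == rid &
                    rs$adrs$pt_code %in% default_term_dictionary()$pt_code, ]
    want <- want + nrow(dr) * nrow(ad)
  }
  expect_equal(nrow(pairs), want)
  expect_true(all(pairs$soc_code > 0))
})

test_that("unknown PT codes are dropped with a logged count, not an error", {
  rs <- make_fixture_reports()
  rs$adrs$pt_code[1] <- 424242L
  expect_message(pairs <- expand_pairs(rs), "unknown")
  expect_equal(attr(pairs, "dropped_unknown_pt"), 1L)
  expect_false(424242L %in% pairs$pt_code)
})

test_that("causality filter keeps possible-or-higher by default", {
  pairs <- random_pair_universe(n = 10, seed = 9)
  pairs$causality <- c(rep("certain", 3), rep("possible", 4),
                       rep("unlikely", 3))
  kept <- filter_causality(pairs)
  expect_equal(nrow(kept), 7)
  expect_false(any(kept$causality == "unlikely"))
  # identity cases
  expect_equal(nrow(filter_causality(pairs, minimum = "unclassified")), 10)
  all_cert <- dplyr::mutate(pairs, causality = "certain")
  expect_equal(filter_causality(all_cert), all_cert)
  # raising the bar can only shrink the universe
  expect_lte(nrow(filter_causality(pairs, minimum = "certain")), nrow(kept))
})

test_that("cleaned, expanded pairs never carry negative onset intervals", {
  cfg <- kaers_like_config(n_reports = 3000, seed = 11)
  rs <- generate_reports(cfg)
  out <- clean_reports(rs, catalog = cfg$catalog)
  pairs <- suppressMessages(
    expand_pairs(out$reports, cfg$dictionary, cfg$catalog))
  expect_true(all(pairs$onset_days >= 0, na.rm = TRUE))
  # the generator planted logical errors; the cascade must have caught some
  expect_gt(out$ledger$excluded_logical_error, 0)
})
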