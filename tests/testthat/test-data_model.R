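test_that("age groups bin decades, floor ages, and send 60+ to '>60'", {
  expect_equal(
    as.character(assign_age_group(c(0, 9.9, 10, 37, 59.9, 60, 65, 99, NA))),
    c("00-09", "00-09", "10-19", "30-39", "50-59", ">60", ">60", ">60",
      "Unknown"))
  expect_error(assign_age_group(-1), class = "asm_validation_error")
})

test_that("age binning is total, disjoint and exhaustive on [0, Inf)", {
  ages <- c(withr::with_seed(1, runif(500, 0, 120)), NA, 0, 60)
  g <- assign_age_group(ages)
  expect_false(anyNA(g))               # every age gets exactly one bin
  expect_setequal(levels(g), age_group_levels())
  # bin membership agrees with direct interval arithmetic
  expect_equal(as.character(g) == ">60", !is.na(ages) & floor(ages) >= 60)
})

test_that("default catalog partitions the 12 study drugs 7/5 by mechanism", {
  cat_ <- asm_catalog()
  expect_equal(nrow(cat_), 12)
  expect_equal(sum(cat_$group == "SCB"), 7)
  expect_equal(sum(cat_$group == "NON_SCB"), 5)
  expect_setequal(cat_$drug_name[cat_$group == "SCB"],
                  c("carbamazepine", "lacosamide", "lamotrigine",
                    "oxcarbazepine", "phenytoin", "topiramate", "valproate"))
  expect_setequal(cat_$drug_name[cat_$group == "NON_SCB"],
                  c("clonazepam", "gabapentin", "levetiracetam",
                    "phenobarbital", "pregabalin"))
})

test_that("drug classification is case-insensitive and fails on unknowns", {
  expect_equal(classify_drug("valproate"), "SCB")
  expect_equal(classify_drug("  Pregabalin "), "NON_SCB")
  expect_equal(classify_drug(c("LAMOTRIGINE", "gabapentin")),
               c("SCB", "NON_SCB"))
  expect_error(classify_drug("aspirin"), class = "asm_lookup_error")
})

test_that("term dictionary enforces one SOC per PT and detects unknown codes", {
  d <- default_term_dictionary()
  expect_true(all(d$soc_code > 0))
  expect_equal(anyDuplicated(d$pt_code), 0)
  hit <- lookup_pt(d, d$pt_code[3])
  expect_equal(hit$pt_name, d$pt_name[3])
  expect_error(lookup_pt(d, 999999L), class = "asm_lookup_error")
  expect_error(
    term_dictionary(tibble::tibble(pt_code = c(1, 1), pt_name = c("a", "b"),
                                   soc_code = c(10, 20),
                                   soc_name = c("x", "y"))),
    class = "asm_dictionary_error")
})

test_that("the sexual/reproductive SOC set defaults to the four codes", {
  expect_setequal(sexual_reproductive_socs(), c(1410L, 1420L, 1500L, 1600L))
  expect_equal(sexual_reproductive_socs(c(1410, 1410)), 1410L)
  expect_error(sexual_reproductive_socs(integer()), class = "asm_config_error")
})

test_that("causality scale is totally ordered with 'possible or higher' ADRs", {
  v <- as_causality(c("certain", "possible", "unlikely", "unclassified"))
  expect_true(v[1] > v[2] && v[2] > v[3] && v[3] > v[4])
  lv <- as_causality(causality_levels())
  expect_equal(as.character(lv[lv >= "possible"]), causality_levels()[4:6])
  expect_error(as_causality("definite"), class = "asm_lookup_error")
})

test_that("write/read round trip is the identity on a canonical report set", {
  rs <- make_fixture_reports()
  dir <- withr::local_tempdir()
  write_reports(rs, dir)
  rs2 <- read_reports(dir)
  expect_equal(rs2, rs)
})

test_that("unknown tokens fall back to 'unknown' with a warning", {
  rs <- make_fixture_reports()
  dir <- withr::local_tempdir()
  write_reports(rs, dir)
  p <- file.path(dir, "reports.csv")
  txt <- sub("clinician", "physician", readLines(p))
  writeLines(txt, p)
  expect_warning(rs2 <- read_reports(dir), "physician")
  expect_equal(rs2$reports$reporter[1], "unknown")
})

test_that("schema violations name the offending column or date", {
  rs <- make_fixture_reports()
  dir <- withr::local_tempdir()
  write_reports(rs, dir)
  p <- file.path(dir, "drugs.csv")
  txt <- readLines(p)
  txt[1] <- sub("drug_name", "drug", txt[1])
  writeLines(txt, p)
  expect_error(read_reports(dir), "drug_name", class = "asm_schema_error")
  write_reports(rs, dir)  # restore
  p <- file.path(dir, "adrs.csv")
  txt <- readLines(p)
  txt[2] <- sub("2018-05-03", "03/05/2018", txt[2])
  writeLines(txt, p)
  expect_error(read_reports(dir), "ISO-8601", class = "asm_schema_error")
})

test_that("one case report keeps all its nested drug entries", {
  rs <- make_fixture_reports()
  expect_equal(sum(rs$drugs$report_id == "F01"), 2)
  expect_equal(sum(rs$adrs$report_id == "F01"), 2)
  expect_error(
    report_set(rs$reports[1:2, ], rs$drugs, rs$adrs),
    class = "asm_integrity_error")
})
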