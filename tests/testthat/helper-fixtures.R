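# Fixture builders and independent oracles shared across test files.
# Everything is built in code; no stored data files.

# a canonical 12-report set exercising NAs, multiple drugs/ADRs per report
make_fixture_reports <- function() {
  reports <- tibble::tibble(
    report_id = sprintf("F%02d", 1:12),
    sex = c("male", "female", "female", "unknown", "male", "female",
            "female", "male", "female", "unknown", "male", "female"),
    age_years = c(34, 62, NA, 7, 45.5, 80, 23, 59, 61, NA, 12, 38),
    reporter = c("clinician", "pharmacist", "nurse", "consumer", "clinician",
                 "pharmacist", "nurse", "other_medical", "pharmacist",
                 "unknown", "clinician", "nurse"),
    serious = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                TRUE, FALSE, FALSE, FALSE),
    serious_categories = c("", "hospitalization", "", "",
                           "death;life_threatening", "", "", "",
                           "other_medical_event", "", "", ""),
    report_date = as.Date("2018-06-01") + c(1:11, NA)
  )
  drugs <- tibble::tibble(
    report_id = c("F01", "F01", "F02", "F03", "F04", "F05", "F06", "F07",
                  "F08", "F09", "F10", "F11", "F12"),
    drug_name = c("valproate", "lamotrigine", "carbamazepine", "pregabalin",
                  "gabapentin", "levetiracetam", "topiramate", "phenytoin",
                  "clonazepam", "oxcarbazepine", "valproate", "lacosamide",
                  "phenobarbital"),
    role = c("suspected", "suspected", "suspected", "suspected", "suspected",
             "concomitant", "suspected", "suspected", "suspected",
             "suspected", "suspected", "suspected", "suspected"),
    start_date = as.Date("2018-05-01") + c(0:5, NA, 7:12)
  )
  d <- asmsignals::default_term_dictionary()
  pt <- function(nm) d$pt_code[match(nm, d$pt_name)]
  adrs <- tibble::tibble(
    report_id = c("F01", "F01", "F02", "F03", "F04", "F05", "F06", "F07",
                  "F08", "F09", "F10", "F11", "F12"),
    pt_code = pt(c("Rash", "Dizziness", "Somnolence", "Dizziness", "Rash",
                   "Nausea", "Tremor", "Urticaria", "Somnolence", "Pruritus",
                   "Menstrual Disorder", "Fever", "Rash")),
    onset_date = as.Date("2018-05-03") + c(0:9, NA, 11:12),
    causality = c("possible", "probable", "certain", "possible", "unlikely",
                  "possible", "probable", "possible", "certain", "possible",
                  "possible", "unassessable", "possible")
  )
  asmsignals::report_set(reports, drugs, adrs)
}

# 12 reports with two planted failures per cleaning stage and four clean ones;
# F.. ids chosen so every report fails at most its intended (first) stage,
# except C01 which also lacks adverse events to check first-stage counting
make_cascade_fixture <- function() {
  d <- asmsignals::default_term_dictionary()
  rash <- d$pt_code[d$pt_name == "Rash"]
  reports <- tibble::tibble(
    report_id = sprintf("C%02d", 1:12),
    sex = c("unknown", "unknown", rep("female", 10)),
    age_years = c(NA, NA, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49),
    reporter = "clinician",
    serious = FALSE,
    serious_categories = "",
    report_date = as.Date("2020-03-01")
  )
  drugs <- tibble::tibble(
    report_id = sprintf("C%02d", 1:12),
    drug_name = c("valproate", "valproate",        # C01 C02 incomplete
                  "valproate", "aspirin",          # C03 concomitant, C04 non-study
                  "valproate", "valproate",        # C05 C06 logical errors
                  "valproate", "valproate",        # C07 C08 missing AE
                  "valproate", "lamotrigine", "gabapentin", "pregabalin"),
    role = c("suspected", "suspected", "concomitant", "suspected",
             rep("suspected", 8)),
    start_date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-01",
                           "2020-01-01", "2020-02-01", "2020-04-01",
                           rep("2020-01-01", 6)))
  )
  adrs <- tibble::tibble(
    report_id = c("C02", "C03", "C04", "C05", "C06",
                  "C09", "C10", "C11", "C12"),
    pt_code = c(NA, rash, rash, rash, rash, rash, rash, rash, rash),
    onset_date = as.Date(c("2020-01-05", "2020-01-05", "2020-01-05",
                           "2020-01-15",  # before C05 start 2020-02-01
                           "2020-04-10", "2020-01-05", "2020-01-05",
                           "2020-01-05", "2020-01-05")),
    causality = "possible"
  )
  # C06: onset after start but report_date (2020-03-01) before start (2020-04-01)
  asmsignals::report_set(reports, drugs, adrs)
}

# random ADR-drug pair universe with every column downstream stages need
random_pair_universe <- function(n = 200, seed = 42, n_drugs = 4,
                                 n_events = 6) {
  withr::with_seed(seed, {
    d <- asmsignals::default_term_dictionary()
    # interleave mechanisms so both groups are always represented
    pool <- c("valproate", "gabapentin", "lamotrigine", "pregabalin",
              "carbamazepine", "clonazepam", "phenytoin", "levetiracetam",
              "oxcarbazepine", "phenobarbital", "topiramate", "lacosamide")
    drugs <- pool[seq_len(n_drugs)]
    evs <- d[seq_len(n_events), ]
    idx <- sample.int(n_events, n, replace = TRUE)
    dn <- sample(drugs, n, replace = TRUE)
    tibble::tibble(
      report_id = sprintf("P%05d", seq_len(n)),
      drug_name = dn,
      group = asmsignals::classify_drug(dn),
      pt_code = evs$pt_code[idx],
      pt_name = evs$pt_name[idx],
      soc_code = evs$soc_code[idx],
      soc_name = evs$soc_name[idx],
      causality = sample(c("possible", "probable", "certain"), n, TRUE),
      sex = sample(c("male", "female"), n, TRUE),
      age_group = asmsignals::assign_age_group(sample(0:80, n, TRUE)),
      reporter = "clinician",
      serious = FALSE,
      serious_categories = "",
      onset_days = sample(c(NA, 0:30), n, TRUE)
    )
  })
}

# a pair universe with exact group x subset marginal counts, for feeding
# printed marginals through the frequency/table operations
marginal_pair_universe <- function(n_scb, n_nonscb, scb_subset = 0,
                                   nonscb_subset = 0,
                                   subset_soc = 1420L, rest_soc = 410L) {
  d <- asmsignals::default_term_dictionary()
  row_for <- function(soc) {
    i <- match(soc, d$soc_code)
    list(pt_code = d$pt_code[i], pt_name = d$pt_name[i],
         soc_name = d$soc_name[i])
  }
  sub <- row_for(subset_soc)
  rest <- row_for(rest_soc)
  grp <- c(rep("SCB", n_scb), rep("NON_SCB", n_nonscb))
  in_sub <- c(rep(TRUE, scb_subset), rep(FALSE, n_scb - scb_subset),
              rep(TRUE, nonscb_subset), rep(FALSE, n_nonscb - nonscb_subset))
  tibble::tibble(
    report_id = sprintf("M%06d", seq_along(grp)),
    drug_name = ifelse(grp == "SCB", "valproate", "gabapentin"),
    group = grp,
    pt_code = ifelse(in_sub, sub$pt_code, rest$pt_code),
    pt_name = ifelse(in_sub, sub$pt_name, rest$pt_name),
    soc_code = ifelse(in_sub, subset_soc, rest_soc),
    soc_name = ifelse(in_sub, sub$soc_name, rest$soc_name),
    causality = "possible",
    sex = "female",
    age_group = asmsignals::assign_age_group(40),
    reporter = "clinician",
    serious = FALSE,
    serious_categories = "",
    onset_days = NA_integer_
  )
}

# ---- independent oracles ----------------------------------------------------

# nested-loop 2x2 count, deliberately naive
brute_force_cells <- function(pairs, drug_set, event_codes,
                              level = c("pt", "soc")) {
  level <- match.arg(level)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(nrow(pairs))) {
    in_d <- pairs$drug_name[i] %in% drug_set
    code <- if (level == "pt") pairs$pt_code[i] else pairs$soc_code[i]
    in_e <- code %in% event_codes
    if (in_d && in_e) a <- a + 1
    else if (in_d) b <- b + 1
    else if (in_e) c_ <- c_ + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = c_, d = d)
}

# textbook formulas, written independently of the package internals
oracle_ror <- function(a, b, c, d) (a * d) / (b * c)
oracle_ror_ci <- function(a, b, c, d, z = qnorm(0.975)) {
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  exp(log((a * d) / (b * c)) + c(-1, 1) * z * se)
}
oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))
oracle_chi2_yates <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  sum(pmax(0, abs(o - e) - 0.5)^2 / e)
}
oracle_ic <- function(a, b, c, d) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  e <- (a + b) * (a + c) / (a + b + c + d)
  ic <- log2((a + 0.5) / (e + 0.5))
  c(ic = ic, ic025 = ic - 3.3 * (a + 0.5)^(-1 / 2) - 2 * (a + 0.5)^(-3 / 2))
}

# two-sided Fisher p by hypergeometric enumeration (small tables only)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n2 <- c + d       # row 2 total
  k <- a + c        # column 1 total
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
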