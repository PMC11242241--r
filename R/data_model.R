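#' WHO-ART-like term dictionary
#'
#' A term dictionary maps adverse-reaction Preferred Term (PT) codes to their
#' PT name and the System Organ Class (SOC) they belong to, mirroring the
#' two-level WHO-ART hierarchy used by national spontaneous-reporting systems.
#'
#' @param entries a data frame with columns `pt_code`, `pt_name`, `soc_code`,
#'   `soc_name`.  Each PT code must map to exactly one SOC; SOC codes must be
#'   positive integers.
#' @return a tibble of class `term_dictionary`.
#' @seealso [default_term_dictionary()], [lookup_pt()]
#' @export
term_dictionary <- function(entries) {
  entries <- as_tibble(entries)
  assert_cols(entries, c("pt_code", "pt_name", "soc_code", "soc_name"),
              "term dictionary")
  entries <- entries %>%
    mutate(pt_code = as.integer(.data$pt_code),
           soc_code = as.integer(.data$soc_code))
  if (anyDuplicated(entries$pt_code)) {
    dup <- unique(entries$pt_code[duplicated(entries$pt_code)])
    abort_asm(sprintf("PT code(s) mapped to more than one entry: %s",
                      paste(dup, collapse = ", ")),
              class = "asm_dictionary_error")
  }
  if (any(is.na(entries$soc_code)) || any(entries$soc_code <= 0)) {
    abort_asm("SOC codes must be positive integers",
              class = "asm_dictionary_error")
  }
  structure(entries, class = c("term_dictionary", class(entries)))
}

#' Built-in adverse-reaction vocabulary
#'
#' A compact WHO-ART-style dictionary covering the reaction terms most often
#' reported for anti-seizure medications: skin, neurological, psychiatric,
#' gastro-intestinal and general disorders, plus the four sexual/reproductive
#' SOCs (male 1410, female 1420, fetal 1500, neonatal/infancy 1600).  PT codes
#' are synthetic (`soc_code * 100 + index`); SOC codes follow the WHO-ART
#' numbering where one exists.
#'
#' @return a [term_dictionary()].
#' @export
default_term_dictionary <- function() {
  soc <- list(
    skin  = c(100L,  "Skin and appendages disorders"),
    cns   = c(410L,  "Central & peripheral nervous system disorders"),
    psych = c(500L,  "Psychiatric disorders"),
    gi    = c(600L,  "Gastro-intestinal system disorders"),
    liver = c(700L,  "Liver and biliary system disorders"),
    wbc   = c(1220L, "White cell and RES disorders"),
    plt   = c(1230L, "Platelet, bleeding & clotting disorders"),
    male  = c(1410L, "Reproductive disorders, male"),
    fem   = c(1420L, "Reproductive disorders, female"),
    fetal = c(1500L, "Fetal disorders"),
    neo   = c(1600L, "Neonatal and infancy disorders"),
    body  = c(1810L, "Body as a whole - general disorders")
  )
  pt <- function(key, idx, name) {
    s <- soc[[key]]
    tibble(pt_code = as.integer(s[1]) * 100L + idx, pt_name = name,
           soc_code = as.integer(s[1]), soc_name = s[2])
  }
  term_dictionary(bind_rows(
    pt("skin", 1L, "Rash"),
    pt("skin", 2L, "Pruritus"),
    pt("skin", 3L, "Urticaria"),
    pt("skin", 4L, "Rash Erythematous"),
    pt("cns", 1L, "Dizziness"),
    pt("cns", 2L, "Somnolence"),
    pt("cns", 3L, "Headache"),
    pt("cns", 4L, "Tremor"),
    pt("cns", 5L, "Paresthesia"),
    pt("psych", 1L, "Insomnia"),
    pt("psych", 2L, "Agitation"),
    pt("psych", 3L, "Depression"),
    pt("psych", 4L, "Aggressive Reaction"),
    pt("psych", 5L, "Amnesia"),
    pt("gi", 1L, "Nausea"),
    pt("gi", 2L, "Vomiting"),
    pt("gi", 3L, "Constipation"),
    pt("gi", 4L, "Dyspepsia"),
    pt("gi", 5L, "Mouth Dry"),
    pt("gi", 6L, "Diarrhea"),
    pt("liver", 1L, "Hepatic Enzymes Increased"),
    pt("wbc", 1L, "Leucopenia"),
    pt("plt", 1L, "Thrombocytopenia"),
    pt("body", 1L, "Fever"),
    pt("body", 2L, "Asthenia"),
    pt("body", 3L, "Face Edema"),
    pt("male", 1L, "Sexual Function Abnormal"),
    pt("fem", 1L, "Menstrual Disorder"),
    pt("fem", 2L, "Amenorrhea"),
    pt("fetal", 1L, "Drug Exposure In Pregnancy"),
    pt("neo", 1L, "Psychomotor Development Impaired")
  ))
}

#' Look up preferred terms in a dictionary
#'
#' Resolves PT codes to `(pt_name, soc_code, soc_name)`.  Unknown codes are a
#' detectable error, never a silent default.
#'
#' @param dictionary a [term_dictionary()].
#' @param pt_code integer vector of PT codes.
#' @return a tibble with one row per element of `pt_code`.
#' @export
lookup_pt <- function(dictionary, pt_code) {
  idx <- match(as.integer(pt_code), dictionary$pt_code)
  if (anyNA(idx)) {
    unknown <- unique(pt_code[is.na(idx)])
    abort_asm(sprintf("unknown PT code(s): %s",
                      paste(unknown, collapse = ", ")),
              class = "asm_lookup_error")
  }
  as_tibble(dictionary)[idx, ]
}

#' Sexual/reproductive SOC set
#'
#' The default set of System Organ Class codes defining sexual/reproductive
#' disorders: male reproductive (1410), female reproductive (1420), fetal
#' (1500), and neonatal and infancy (1600) disorders.
#'
#' @param soc_codes integer vector overriding the default set.
#' @return an integer vector of SOC codes.
#' @export
sexual_reproductive_socs <- function(soc_codes = c(1410L, 1420L, 1500L, 1600L)) {
  soc_codes <- as.integer(soc_codes)
  if (length(soc_codes) == 0 || any(is.na(soc_codes)) || any(soc_codes <= 0)) {
    abort_asm("SOC codes must be a nonempty set of positive integers",
              class = "asm_config_error")
  }
  unique(soc_codes)
}

#' Anti-seizure medication catalog
#'
#' The default study catalog contains the 12 anti-seizure medications (ASMs),
#' partitioned by mechanism of action into sodium channel blockers (`"SCB"`:
#' carbamazepine, lacosamide, lamotrigine, oxcarbazepine, phenytoin,
#' topiramate, valproate) and other mechanisms (`"NON_SCB"`: clonazepam,
#' gabapentin, levetiracetam, phenobarbital, pregabalin).
#'
#' @param drugs optional data frame with columns `drug_name`, `group`
#'   (values `"SCB"` or `"NON_SCB"`) replacing the default catalog.
#' @return a tibble of class `drug_catalog`.
#' @export
asm_catalog <- function(drugs = NULL) {
  if (is.null(drugs)) {
    drugs <- tibble(
      drug_name = c("carbamazepine", "lacosamide", "lamotrigine",
                    "oxcarbazepine", "phenytoin", "topiramate", "valproate",
                    "clonazepam", "gabapentin", "levetiracetam",
                    "phenobarbital", "pregabalin"),
      group = c(rep("SCB", 7), rep("NON_SCB", 5))
    )
  }
  drugs <- as_tibble(drugs)
  assert_cols(drugs, c("drug_name", "group"), "drug catalog")
  drugs <- drugs %>% mutate(drug_name = normalize_drug(.data$drug_name))
  if (!all(drugs$group %in% c("SCB", "NON_SCB"))) {
    abort_asm('drug catalog groups must be "SCB" or "NON_SCB"',
              class = "asm_config_error")
  }
  if (anyDuplicated(drugs$drug_name)) {
    abort_asm("duplicate drug names in catalog", class = "asm_config_error")
  }
  structure(drugs, class = c("drug_catalog", class(drugs)))
}

normalize_drug <- function(x) tolower(trimws(x))

#' Classify a drug by mechanism group
#'
#' Case-insensitive exact match on the active-substance name; no salt-form
#' parsing.  A drug absent from the catalog raises a lookup error so the
#' caller decides whether to skip or fail.
#'
#' @param name character vector of drug names.
#' @param catalog a [asm_catalog()].
#' @return character vector of `"SCB"` / `"NON_SCB"`.
#' @export
#' @examples
#' classify_drug(c("Valproate", "pregabalin"))
classify_drug <- function(name, catalog = asm_catalog()) {
  idx <- match(normalize_drug(name), catalog$drug_name)
  if (anyNA(idx)) {
    unknown <- unique(name[is.na(idx)])
    abort_asm(sprintf("drug(s) not in catalog: %s",
                      paste(unknown, collapse = ", ")),
              class = "asm_lookup_error")
  }
  catalog$group[idx]
}

#' WHO-UMC causality categories
#'
#' Ordered assessment scale, ascending: unclassified < unassessable <
#' unlikely < possible < probable < certain.  An adverse event counts as an
#' adverse drug reaction only when its causality is "possible" or higher.
#'
#' @return character vector of levels in ascending order.
#' @export
causality_levels <- function() {
  c("unclassified", "unassessable", "unlikely",
    "possible", "probable", "certain")
}

#' Coerce to an ordered causality factor
#'
#' @param x character vector of causality category names.
#' @return ordered factor over [causality_levels()].
#' @export
as_causality <- function(x) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x[!is.na(x)]), causality_levels())
  if (length(bad) > 0) {
    abort_asm(sprintf("unknown causality categor(ies): %s",
                      paste(bad, collapse = ", ")),
              class = "asm_lookup_error")
  }
  factor(x, levels = causality_levels(), ordered = TRUE)
}

#' Age-group labels
#'
#' @return character vector of the decade age-group labels in display order.
#' @export
age_group_levels <- function() {
  c("00-09", "10-19", "20-29", "30-39", "40-49", "50-59", ">60", "Unknown")
}

#' Assign decade age groups
#'
#' Ages are floored to integer years, then binned into decades 00-09 through
#' 50-59; any age of 60 years or more falls in ">60"; missing ages map to
#' "Unknown".  Bins are disjoint and exhaustive on `[0, Inf)` plus missing.
#'
#' @param age_years numeric vector of ages in years (NA allowed).
#' @return factor over [age_group_levels()].
#' @export
#' @examples
#' assign_age_group(c(0, 9.9, 59.9, 60, 65, NA))
assign_age_group <- function(age_years) {
  if (any(age_years < 0, na.rm = TRUE)) {
    abort_asm("age_years must be nonnegative", class = "asm_validation_error")
  }
  yrs <- floor(age_years)
  lab <- ifelse(is.na(yrs), "Unknown",
         ifelse(yrs >= 60, ">60",
                sprintf("%02d-%02d", (yrs %/% 10) * 10, (yrs %/% 10) * 10 + 9)))
  factor(lab, levels = age_group_levels())
}

# vocabularies for report fields
sex_levels <- function() c("male", "female", "unknown")
reporter_levels <- function() {
  c("clinician", "pharmacist", "nurse", "other_medical", "consumer", "unknown")
}
role_levels <- function() c("suspected", "concomitant")
seriousness_categories <- function() {
  c("death", "life_threatening", "hospitalization", "disability",
    "congenital_anomaly", "other_medical_event")
}
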