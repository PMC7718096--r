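#' Built-in drug catalog
#'
#' A small formulary covering the therapeutic classes that dominate serious
#' drug-drug interaction (DDI) alerting in retail pharmacy data: macrolide and
#' quinolone antibiotics, opioids, erectile-dysfunction (ED) and pulmonary
#' arterial hypertension (PAH) products, nitrate vasodilators, plus common
#' chronic-therapy classes (statins, antihypertensives, etc.) that form the
#' background prescription stream. `condition_group` is the explicit
#' therapeutic-equivalence map used when classifying an alert disposition as a
#' replacement.
#'
#' @return A tibble with columns `drug_id`, `therapeutic_class`,
#'   `condition_group`, `typical_days_supply`.
#' @export
#' @examples
#' default_drug_catalog()
default_drug_catalog <- function() {
  tibble::tribble(
    ~drug_id,                 ~therapeutic_class,     ~condition_group,         ~typical_days_supply,
    "azithromycin",           "macrolide",            "bacterial_infection",    10L,
    "clarithromycin",         "macrolide",            "bacterial_infection",    10L,
    "ciprofloxacin",          "quinolone",            "bacterial_infection",    10L,
    "levofloxacin",           "quinolone",            "bacterial_infection",    10L,
    "tramadol",               "opioid_analgesic",     "pain",                   30L,
    "oxycodone",              "opioid_analgesic",     "pain",                   30L,
    "apap_codeine",           "opioid_nonsalicylate", "pain",                   15L,
    "sildenafil_ed",          "ED",                   "erectile_dysfunction",   30L,
    "tadalafil_ed",           "ED",                   "erectile_dysfunction",   30L,
    "sildenafil_pah",         "PAH",                  "pulmonary_hypertension", 30L,
    "nitroglycerin",          "vasodilator",          "angina",                 30L,
    "isosorbide_mononitrate", "vasodilator",          "angina",                 30L,
    "alprazolam",             "benzodiazepine",       "anxiety",                30L,
    "diazepam",               "benzodiazepine",       "anxiety",                30L,
    "amiodarone",             "antiarrhythmic",       "arrhythmia",             90L,
    "atorvastatin",           "statin",               "hyperlipidemia",         90L,
    "simvastatin",            "statin",               "hyperlipidemia",         90L,
    "amlodipine",             "ccb",                  "hypertension",           90L,
    "lisinopril",             "ace_inhibitor",        "hypertension",           90L,
    "metformin",              "biguanide",            "diabetes",               90L,
    "levothyroxine",          "thyroid_hormone",      "hypothyroidism",         90L,
    "sertraline",             "ssri",                 "depression",             30L
  )
}

#' Built-in serious drug-drug interaction table
#'
#' Class-pair interactions screened at SERIOUS severity. The table stands in
#' for a commercial DDI knowledge base; pairs are chosen to be
#' pharmacologically plausible (macrolide-statin, nitrate-PDE5 inhibitor,
#' opioid-benzodiazepine, QT-prolonging antibiotic-antiarrhythmic). The
#' `plant_weight` column steers how often the claim generator plants each pair
#' so the synthetic alert class mix resembles retail DUR alert volumes
#' (antibiotics most common, then opioids, then ED/PAH/vasodilators).
#'
#' @return A tibble with columns `class_a`, `class_b`, `severity`,
#'   `plant_weight`. Stored one row per unordered pair; screening resolves the
#'   symmetric closure via [symmetrize_interactions()].
#' @export
default_interaction_table <- function() {
  tibble::tribble(
    ~class_a,               ~class_b,         ~severity,  ~plant_weight,
    "macrolide",            "statin",         "SERIOUS",  0.28,
    "quinolone",            "antiarrhythmic", "SERIOUS",  0.16,
    "macrolide",            "antiarrhythmic", "SERIOUS",  0.06,
    "opioid_analgesic",     "benzodiazepine", "SERIOUS",  0.12,
    "opioid_nonsalicylate", "benzodiazepine", "SERIOUS",  0.12,
    "ED",                   "vasodilator",    "SERIOUS",  0.17,
    "PAH",                  "vasodilator",    "SERIOUS",  0.09
  )
}

#' Symmetric closure of an interaction table
#'
#' Expands each unordered class pair to both orientations and drops
#' duplicates, so a directional join `(class of incoming, class of history)`
#' can resolve either orientation. Self-pairs are rejected.
#'
#' @param interactions tibble with columns `class_a`, `class_b`, `severity`.
#' @return tibble with both orientations of every pair.
#' @export
symmetrize_interactions <- function(interactions) {
  check_cols(interactions, c("class_a", "class_b", "severity"), "interaction table")
  if (any(interactions$class_a == interactions$class_b)) {
    stop("interaction table must not contain self-pairs", call. = FALSE)
  }
  both <- dplyr::bind_rows(
    interactions,
    dplyr::rename(interactions, class_a = "class_b", class_b = "class_a")
  )
  dplyr::distinct(both, .data$class_a, .data$class_b, .keep_all = TRUE)
}

validate_catalog <- function(catalog) {
  check_cols(catalog, c("drug_id", "therapeutic_class", "condition_group",
                        "typical_days_supply"), "drug catalog")
  if (anyDuplicated(catalog$drug_id)) {
    stop("each drug_id must map to exactly one class and condition group",
         call. = FALSE)
  }
  invisible(catalog)
}

#' Read or write an interaction table as CSV
#'
#' @param path file path.
#' @param interactions tibble as produced by [default_interaction_table()].
#' @return `read_interactions()` returns a tibble; `write_interactions()`
#'   returns `path` invisibly.
#' @export
read_interactions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    class_a = readr::col_character(),
    class_b = readr::col_character(),
    severity = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' @rdname read_interactions
#' @export
write_interactions <- function(interactions, path) {
  readr::write_csv(interactions, path)
  invisible(path)
}
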