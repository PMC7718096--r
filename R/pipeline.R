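# End-to-end orchestration: simulate -> link -> screen -> classify ->
# estimate -> report.

#' Pipeline run configuration
#'
#' Bundles every stage's configuration plus the root seed. The object is
#' plain-list serializable, so a run is fully described by its config and
#' can be reproduced byte-for-byte.
#'
#' @param seed integer root seed for all stages.
#' @param n_patients synthetic population size.
#' @param churn a [churn_config()].
#' @param dur a [dur_config()].
#' @param outcome an [outcome_config()].
#' @param ddi_plant_rate per-patient probability of a planted interacting
#'   pair; passed to [simulate_claims()].
#' @param fills_per_year background fill intensity.
#' @param typo_rate demographic corruption rate applied before linkage.
#' @param projection named list of overrides for [project_national()]
#'   (e.g. `market_share_override`, `abandonment_prop`).
#' @param out_dir optional output directory; when given, [run_pipeline()]
#'   writes the CSV/JSON report bundle there.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_patients = 2000L,
                       churn = churn_config(), dur = dur_config(),
                       outcome = outcome_config(),
                       ddi_plant_rate = 0.15, fills_per_year = 3,
                       typo_rate = 0, projection = list(),
                       out_dir = NULL) {
  stopifnot(inherits(churn, "churn_config"), inherits(dur, "dur_config"),
            inherits(outcome, "outcome_config"))
  check_prob(typo_rate, "typo_rate")
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         churn = churn, dur = dur, outcome = outcome,
         ddi_plant_rate = ddi_plant_rate, fills_per_year = fills_per_year,
         typo_rate = typo_rate, projection = projection, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full crossover-alert pipeline
#'
#' Executes the whole study sequence on synthetic data: generate a
#' population and claims, optionally corrupt demographics, link under both
#' identity regimes, screen for serious-DDI alerts under each regime,
#' classify dispositions of the UPI-regime alerts, tabulate stratified
#' rates, and run the national projection on the simulated counts. When
#' `config$out_dir` is set, the bundle is written as CSV/JSON files plus a
#' `manifest.json` recording an MD5 checksum per file, so reruns can be
#' verified byte-for-byte.
#'
#' @param config a [run_config()].
#' @param catalog,interactions drug catalog and interaction table.
#' @return invisible list with `claims`, `truth`, `map_beneficiary`,
#'   `map_upi`, `alerts_beneficiary`, `alerts_upi`, `dispositions`, `rates`,
#'   `linkage_quality`, `projection`, `counters`, and `manifest` (when
#'   written).
#' @export
run_pipeline <- function(config = run_config(),
                         catalog = default_drug_catalog(),
                         interactions = default_interaction_table()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  pop <- stage("simulate", generate_population(config$n_patients, config$churn,
                                               seed = config$seed))
  sim <- stage("simulate", simulate_claims(
    pop, catalog = catalog, interactions = interactions,
    ddi_plant_rate = config$ddi_plant_rate,
    fills_per_year = config$fills_per_year,
    dur = config$dur, seed = config$seed))
  claims <- stage("perturb",
                  perturb_demographics(sim$claims, config$typo_rate,
                                       seed = config$seed))

  if (nrow(claims) == 0) stop("[simulate] produced an empty claim stream", call. = FALSE)
  map_ben <- stage("link", link_by_beneficiary(claims))
  map_upi <- stage("link", link_by_upi(claims))
  lq <- stage("link", linkage_quality(
    map_upi, claims[c("claim_id", "true_patient_key")]))

  alerts_ben <- stage("screen", run_pdur(claims, map_ben, interactions, config$dur))
  alerts_upi <- stage("screen", run_pdur(claims, map_upi, interactions, config$dur))

  disp <- stage("classify", classify_outcomes(alerts_upi, claims, map_upi,
                                              config$outcome))
  rates <- if (nrow(alerts_upi) > 0) {
    stage("classify", tabulate_rates(alerts_upi, disp, claims))
  } else {
    NULL
  }

  horizon_years <- as.numeric(config$churn$horizon_end -
                                config$churn$horizon_start + 1) / 365.25
  proj_args <- utils::modifyList(
    list(
      n_alerts_total = nrow(alerts_upi),
      n_crossover = sum(alerts_upi$crossover),
      study_years = horizon_years,
      market_share_override = 0.165,
      abandonment_prop = if (nrow(alerts_upi) > 0) mean(disp$outcome == "ABANDONMENT") else 0,
      replacement_prop = if (nrow(alerts_upi) > 0) mean(disp$outcome == "REPLACEMENT") else 0
    ),
    config$projection
  )
  proj <- stage("estimate", do.call(project_national, proj_args))

  counters <- list(
    n_patients = config$n_patients,
    n_claims = nrow(claims),
    n_alerts_beneficiary = nrow(alerts_ben),
    n_alerts_upi = nrow(alerts_upi),
    n_crossover = sum(alerts_upi$crossover),
    crossover_rate = if (nrow(alerts_upi) > 0) mean(alerts_upi$crossover) else 0
  )

  bundle <- list(claims = claims, truth = sim$truth,
                 map_beneficiary = map_ben, map_upi = map_upi,
                 alerts_beneficiary = alerts_ben, alerts_upi = alerts_upi,
                 dispositions = disp, rates = rates, linkage_quality = lq,
                 projection = proj, counters = counters)

  if (!is.null(config$out_dir)) {
    bundle$manifest <- stage("report", write_bundle(bundle, config))
  }
  invisible(bundle)
}

serialize_config <- function(config) {
  to_plain <- function(x) {
    if (inherits(x, "Date")) return(as.character(x))
    if (is.list(x)) return(lapply(unclass(x), to_plain))
    x
  }
  plain <- to_plain(unclass(config))
  plain$out_dir <- NULL # location of the bundle, not part of its content
  jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, null = "null")
}

write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)

  write_claims(bundle$claims, path("claims.csv"))
  readr::write_csv(bundle$truth, path("ground_truth.csv"))
  write_linkage_map(bundle$map_beneficiary, path("linkage_beneficiary.csv"))
  write_linkage_map(bundle$map_upi, path("linkage_upi.csv"))
  write_alerts(bundle$alerts_beneficiary, path("alerts_beneficiary.csv"))
  write_alerts(bundle$alerts_upi, path("alerts_upi.csv"))
  readr::write_csv(bundle$dispositions, path("dispositions.csv"))
  if (!is.null(bundle$rates)) readr::write_csv(bundle$rates, path("rates.csv"))
  jsonlite::write_json(unclass(bundle$projection), path("projection.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_json <- serialize_config(config)
  cfg_file <- path("config.json")
  writeLines(cfg_json, cfg_file)

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  checksums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("durlink")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = stats::setNames(as.list(unname(checksums)), files)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  manifest
}
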