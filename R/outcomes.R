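# Alert dispositions and stratified rate tabulation.

#' Classify alert dispositions from subsequent claims
#'
#' For each alert, searches the claims of the alert's identity within the
#' half-open window `(alert_date, alert_date + outcome_window]` and assigns:
#'
#' * `OVERRIDE` — the same drug (by `drug_id`, or by therapeutic class if
#'   `config$override_same_class`) was dispensed in the window: the pharmacy
#'   reviewed the conflict and dispensed anyway;
#' * `REPLACEMENT` — a different drug with the same `condition_group` was
#'   dispensed in the window;
#' * `ABANDONMENT` — neither occurred.
#'
#' Precedence is fixed `OVERRIDE > REPLACEMENT`. The resolving claim recorded
#' is the earliest qualifying fill of the winning kind (ties by claim id).
#'
#' @param ledger alert ledger from [run_pdur()].
#' @param claims claim stream tibble.
#' @param map linkage map under which resolutions are sought (normally the
#'   UPI map, so a resolution filled under new insurance still counts).
#' @param config an [outcome_config()].
#' @return tibble `alert_id`, `outcome`, `resolving_claim_id` (`NA` for
#'   abandonment), one row per alert.
#' @export
classify_outcomes <- function(ledger, claims, map, config = outcome_config()) {
  check_cols(ledger, c("alert_id", "triggering_claim_id", "alert_date"), "ledger")
  if (nrow(ledger) == 0) {
    return(tibble::tibble(alert_id = integer(), outcome = character(),
                          resolving_claim_id = integer()))
  }
  linked <- dplyr::inner_join(claims, map[c("claim_id", "identity_key")],
                              by = "claim_id")
  trig <- linked |>
    dplyr::select(triggering_claim_id = "claim_id", identity_key = "identity_key",
                  trig_drug = "drug_id", trig_class = "therapeutic_class",
                  trig_group = "condition_group")
  alerts <- dplyr::inner_join(ledger, trig, by = "triggering_claim_id")

  cand <- linked |>
    dplyr::select(identity_key = "identity_key", res_id = "claim_id",
                  res_date = "fill_date", res_drug = "drug_id",
                  res_class = "therapeutic_class", res_group = "condition_group")
  hits <- alerts |>
    dplyr::select("alert_id", "identity_key", "alert_date", "trig_drug",
                  "trig_class", "trig_group") |>
    dplyr::inner_join(cand, by = "identity_key", relationship = "many-to-many") |>
    dplyr::filter(.data$res_date > .data$alert_date,
                  .data$res_date <= .data$alert_date + config$outcome_window) |>
    dplyr::mutate(
      is_override = if (config$override_same_class) {
        .data$res_class == .data$trig_class
      } else {
        .data$res_drug == .data$trig_drug
      },
      is_replacement = !.data$is_override &
        .data$res_group == .data$trig_group &
        .data$res_drug != .data$trig_drug
    ) |>
    dplyr::filter(.data$is_override | .data$is_replacement) |>
    dplyr::arrange(.data$alert_id, dplyr::desc(.data$is_override),
                   .data$res_date, .data$res_id) |>
    dplyr::distinct(.data$alert_id, .keep_all = TRUE) |>
    dplyr::transmute(
      alert_id = .data$alert_id,
      outcome = dplyr::if_else(.data$is_override, "OVERRIDE", "REPLACEMENT"),
      resolving_claim_id = .data$res_id
    )

  ledger |>
    dplyr::select("alert_id") |>
    dplyr::left_join(hits, by = "alert_id") |>
    dplyr::mutate(outcome = dplyr::coalesce(.data$outcome, "ABANDONMENT"))
}

#' Tabulate crossover and disposition rates by stratum
#'
#' Computes, per stratum of the triggering claim (calendar month of the alert
#' date, age at alert, benefit type, therapeutic class, sex) plus an overall
#' row: the number of alerts, crossover alerts and crossover rate, and the
#' counts and proportions of each disposition. Proportions are returned at
#' full precision; use [round_half_up()] for one-decimal reporting.
#'
#' @param ledger alert ledger.
#' @param dispositions output of [classify_outcomes()] covering the ledger.
#' @param claims claim stream (source of stratum attributes).
#' @param strata which stratifications to compute.
#' @return tibble with columns `stratum`, `level`, `n_alerts`, `n_crossover`,
#'   `crossover_rate`, `n_override`, `n_replacement`, `n_abandonment`,
#'   `prop_override`, `prop_replacement`, `prop_abandonment`.
#' @export
tabulate_rates <- function(ledger, dispositions, claims,
                           strata = c("overall", "month", "age", "benefit_type",
                                      "therapeutic_class", "sex")) {
  strata <- match.arg(strata, several.ok = TRUE)
  attrs <- claims |>
    dplyr::select(triggering_claim_id = "claim_id", "benefit_type",
                  "birth_date", "sex", therapeutic_class = "therapeutic_class")
  df <- ledger |>
    dplyr::inner_join(dispositions, by = "alert_id") |>
    dplyr::inner_join(attrs, by = "triggering_claim_id") |>
    dplyr::mutate(
      month = as.integer(format(.data$alert_date, "%m")),
      age = age_at(.data$birth_date, .data$alert_date)
    )
  if (nrow(df) < nrow(ledger)) {
    stop("`dispositions` and `claims` must cover every alert", call. = FALSE)
  }
  one <- function(g) {
    df |>
      dplyr::mutate(level = as.character(if (g == "overall") "overall" else .data[[g]])) |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(
        n_alerts = dplyr::n(),
        n_crossover = sum(.data$crossover),
        n_override = sum(.data$outcome == "OVERRIDE"),
        n_replacement = sum(.data$outcome == "REPLACEMENT"),
        n_abandonment = sum(.data$outcome == "ABANDONMENT"),
        .groups = "drop"
      ) |>
      dplyr::mutate(stratum = g)
  }
  out <- dplyr::bind_rows(lapply(strata, one)) |>
    dplyr::mutate(
      crossover_rate = .data$n_crossover / .data$n_alerts,
      prop_override = .data$n_override / .data$n_alerts,
      prop_replacement = .data$n_replacement / .data$n_alerts,
      prop_abandonment = .data$n_abandonment / .data$n_alerts
    ) |>
    dplyr::select("stratum", "level", "n_alerts", "n_crossover",
                  "crossover_rate", "n_override", "n_replacement",
                  "n_abandonment", "prop_override", "prop_replacement",
                  "prop_abandonment")
  out
}

#' Monthly crossover rate series
#'
#' Convenience extraction of the month stratum of [tabulate_rates()] ordered
#' January through December, for plotting seasonal crossover patterns.
#'
#' @inheritParams tabulate_rates
#' @return tibble `month` (1-12), `n_alerts`, `n_crossover`, `crossover_rate`.
#' @export
monthly_crossover_series <- function(ledger, dispositions, claims) {
  tabulate_rates(ledger, dispositions, claims, strata = "month") |>
    dplyr::mutate(month = as.integer(.data$level)) |>
    dplyr::arrange(.data$month) |>
    dplyr::select("month", "n_alerts", "n_crossover", "crossover_rate")
}
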