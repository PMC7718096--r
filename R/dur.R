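# Prospective drug utilization review engine.
#
# Claims are screened in fill-date order against the prescription history of
# the identity they map to; each SERIOUS class-pair match between the
# incoming claim and an active historical fill emits one alert.

#' Active prescription history for an identity at a date
#'
#' Returns the claims that count as history for screening a fill on `as_of`:
#' filled strictly before `as_of`, within the lookback window
#' (`fill_date >= as_of - history_window`), and still on hand when required
#' (`fill_date + days_supply >= as_of`).
#'
#' @param identity_claims claims of a single identity.
#' @param as_of screening date (`Date`).
#' @param config a [dur_config()].
#' @return the qualifying subset of `identity_claims`.
#' @export
active_history <- function(identity_claims, as_of, config = dur_config()) {
  check_cols(identity_claims, c("fill_date", "days_supply"), "identity_claims")
  as_of <- as.Date(as_of)
  keep <- identity_claims$fill_date < as_of &
    identity_claims$fill_date >= as_of - config$history_window
  if (config$require_active_supply) {
    keep <- keep & identity_claims$fill_date + identity_claims$days_supply >= as_of
  }
  identity_claims[keep, , drop = FALSE]
}

#' Screen one incoming claim against a prescription history
#'
#' Emits one alert per history claim whose therapeutic class forms a SERIOUS
#' pair with the incoming claim's class, ordered by precipitating claim id.
#' An incoming claim whose class is absent from the interaction table
#' produces no alert (a warning is raised, since it usually indicates a
#' catalog/table mismatch).
#'
#' @param incoming a single-row claim tibble.
#' @param history claims from [active_history()] at the incoming fill date.
#' @param interactions interaction table.
#' @return tibble of alerts (possibly empty): `triggering_claim_id`,
#'   `precipitating_claim_id`, `alert_date`, `class_triggering`,
#'   `class_precipitating`.
#' @export
screen_claim <- function(incoming, history, interactions) {
  stopifnot(nrow(incoming) == 1)
  sym <- symmetrize_interactions(interactions)
  sym <- sym[sym$severity == "SERIOUS", , drop = FALSE]
  if (!incoming$therapeutic_class %in% unique(c(sym$class_a, sym$class_b))) {
    warning(sprintf("therapeutic class '%s' not present in the interaction table",
                    incoming$therapeutic_class))
  }
  partners <- sym$class_b[sym$class_a == incoming$therapeutic_class]
  hits <- history[history$therapeutic_class %in% partners, , drop = FALSE]
  hits <- hits[order(hits$claim_id), , drop = FALSE]
  tibble::tibble(
    triggering_claim_id = rep(incoming$claim_id, nrow(hits)),
    precipitating_claim_id = hits$claim_id,
    alert_date = rep(incoming$fill_date, nrow(hits)),
    class_triggering = rep(incoming$therapeutic_class, nrow(hits)),
    class_precipitating = hits$therapeutic_class
  )
}

#' Run prospective DUR over a claim stream
#'
#' Processes claims in fill-date order (ties by claim id) under the identity
#' assignment of `map`, screening each claim against the active history of
#' its identity and emitting one alert per (triggering, precipitating) pair
#' of interacting fills. On the same day, the precipitating claim is the one
#' with the smaller claim id, so a pair is never counted in both directions.
#' Alerts carry a crossover flag: true when the triggering and precipitating
#' claims were adjudicated under different `(payor_id, beneficiary_id)`
#' identifiers — such alerts are discoverable only when the identity regime
#' links records across insurance changes.
#'
#' @param claims claim stream tibble.
#' @param map linkage map covering every claim.
#' @param interactions interaction table.
#' @param config a [dur_config()].
#' @return alert ledger tibble: `alert_id`, `triggering_claim_id`,
#'   `precipitating_claim_id`, `alert_date`, `class_triggering`,
#'   `class_precipitating`, `crossover`, `regime`.
#' @export
run_pdur <- function(claims, map, interactions, config = dur_config()) {
  check_cols(claims, c("claim_id", "fill_date", "therapeutic_class",
                       "days_supply", "payor_id", "beneficiary_id"), "claims")
  check_cols(map, c("claim_id", "identity_key", "regime"), "map")
  regime <- unique(map$regime)
  if (length(regime) != 1) stop("`map` must carry a single regime", call. = FALSE)
  linked <- dplyr::inner_join(claims, map[c("claim_id", "identity_key")],
                              by = "claim_id")
  if (nrow(linked) < nrow(claims)) {
    stop("`map` must cover every claim", call. = FALSE)
  }
  sym <- symmetrize_interactions(interactions)
  sym <- sym[sym$severity == "SERIOUS", c("class_a", "class_b")]

  trig <- linked |>
    dplyr::select(identity_key = "identity_key", t_id = "claim_id",
                  t_date = "fill_date", t_class = "therapeutic_class",
                  t_payor = "payor_id", t_ben = "beneficiary_id")
  prec <- linked |>
    dplyr::select(identity_key = "identity_key", p_id = "claim_id",
                  p_date = "fill_date", p_class = "therapeutic_class",
                  p_ds = "days_supply", p_payor = "payor_id",
                  p_ben = "beneficiary_id")
  pairs <- dplyr::inner_join(trig, prec, by = "identity_key",
                             relationship = "many-to-many") |>
    dplyr::filter(
      .data$p_date < .data$t_date |
        (.data$p_date == .data$t_date & .data$p_id < .data$t_id),
      .data$p_date >= .data$t_date - config$history_window
    )
  if (config$require_active_supply) {
    pairs <- dplyr::filter(pairs, .data$p_date + .data$p_ds >= .data$t_date)
  }
  ledger <- pairs |>
    dplyr::inner_join(sym, by = c(t_class = "class_a", p_class = "class_b")) |>
    dplyr::transmute(
      triggering_claim_id = .data$t_id,
      precipitating_claim_id = .data$p_id,
      alert_date = .data$t_date,
      class_triggering = .data$t_class,
      class_precipitating = .data$p_class,
      crossover = .data$t_payor != .data$p_payor | .data$t_ben != .data$p_ben
    ) |>
    dplyr::arrange(.data$alert_date, .data$triggering_claim_id,
                   .data$precipitating_claim_id) |>
    dplyr::mutate(alert_id = dplyr::row_number(), regime = regime) |>
    dplyr::select("alert_id", dplyr::everything())
  ledger
}

#' Recompute the crossover flag of alerts from their claims
#'
#' An alert is a crossover alert when its triggering and precipitating claims
#' carry different `(payor_id, beneficiary_id)` identifiers, i.e. the
#' precipitating fill would be invisible to a review keyed on the insurance
#' identifier alone.
#'
#' @param ledger alert ledger tibble.
#' @param claims claim stream the ledger refers to.
#' @return logical vector, one element per alert.
#' @export
flag_crossover <- function(ledger, claims) {
  ids <- claims[c("claim_id", "payor_id", "beneficiary_id")]
  t <- dplyr::left_join(ledger["triggering_claim_id"], ids,
                        by = c(triggering_claim_id = "claim_id"))
  p <- dplyr::left_join(ledger["precipitating_claim_id"], ids,
                        by = c(precipitating_claim_id = "claim_id"))
  t$payor_id != p$payor_id | t$beneficiary_id != p$beneficiary_id
}

#' Write an alert ledger as CSV
#'
#' @param ledger alert ledger tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_alerts <- function(ledger, path) {
  out <- ledger |>
    dplyr::mutate(class_pair = paste(.data$class_triggering,
                                     .data$class_precipitating, sep = ":")) |>
    dplyr::select("alert_id", "triggering_claim_id", "precipitating_claim_id",
                  "alert_date", "class_pair", "crossover", "regime")
  readr::write_csv(out, path)
  invisible(path)
}
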