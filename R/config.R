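#' Insurance churn configuration
#'
#' Controls how synthetic patients move between payors and benefits over the
#' simulation horizon. The defaults emulate US commercial/government pharmacy
#' benefit dynamics: roughly a fifth of patients change insurance in a year,
#' plan changes cluster on January 1 (open enrollment), extra transitions occur
#' at ages 19 and 26 (ageing off family plans) and 65 (Medicare eligibility),
#' and Medicaid churn shows no open-enrollment seasonality. Erectile
#' dysfunction products are frequently non-covered and are filled under an
#' alternate cash/coupon identifier with probability
#' `offbenefit_classes["ED"]`. The January concentration and off-benefit
#' rate defaults are calibrated so the simulated alert stream reproduces the
#' qualitative structure of observed retail DUR data: crossover alerts
#' roughly 2-2.5 times as likely in January as in other months, and
#' ED-involved alerts several times more likely to cross identifiers than
#' other classes.
#'
#' @param annual_transition_prob probability per patient-year of a payor
#'   transition (0.2 by default, consistent with observed year-over-year PBM
#'   cohort attrition of roughly 19%).
#' @param january_concentration fraction of non-Medicaid transitions that take
#'   effect on January 1; the remainder are uniform over the year.
#' @param age_triggers named numeric vector of per-age transition
#'   probabilities applied at the birthday when a patient turns that age.
#' @param benefit_mix named probabilities over benefit types
#'   `MEDICAID`, `EXCHANGE`, `MEDICARE_D`, `OTHER`; must sum to 1.
#' @param medicaid_seasonality_flat if `TRUE`, Medicaid transitions ignore
#'   `january_concentration` (Medicaid enrollment is year-round).
#' @param offbenefit_classes named probabilities, per therapeutic class, that
#'   a fill of that class is adjudicated under an alternate cash/coupon
#'   identifier rather than the active benefit.
#' @param payor_pool_size,pbm_pool_size sizes of the payor and PBM universes;
#'   each payor is served by one PBM.
#' @param horizon_start,horizon_end simulation window (`Date`); defaults to a
#'   3-year window from 2016-09-01 to 2019-08-31.
#' @return an object of class `churn_config` (a validated list).
#' @export
#' @examples
#' churn_config(annual_transition_prob = 0.3)
churn_config <- function(annual_transition_prob = 0.2,
                         january_concentration = 0.7,
                         age_triggers = c(`19` = 0.6, `26` = 0.5, `65` = 0.9),
                         benefit_mix = c(MEDICAID = 0.15, EXCHANGE = 0.05,
                                         MEDICARE_D = 0.15, OTHER = 0.65),
                         medicaid_seasonality_flat = TRUE,
                         offbenefit_classes = c(ED = 0.1),
                         payor_pool_size = 200L,
                         pbm_pool_size = 4L,
                         horizon_start = as.Date("2016-09-01"),
                         horizon_end = as.Date("2019-08-31")) {
  check_prob(annual_transition_prob, "annual_transition_prob")
  check_prob(january_concentration, "january_concentration")
  check_prob(age_triggers, "age_triggers")
  check_prob(benefit_mix, "benefit_mix")
  if (length(offbenefit_classes) > 0) check_prob(offbenefit_classes, "offbenefit_classes")
  if (abs(sum(benefit_mix) - 1) > 1e-8) {
    stop("`benefit_mix` must sum to 1", call. = FALSE)
  }
  if (!setequal(names(benefit_mix), c("MEDICAID", "EXCHANGE", "MEDICARE_D", "OTHER"))) {
    stop("`benefit_mix` must name MEDICAID, EXCHANGE, MEDICARE_D, OTHER", call. = FALSE)
  }
  horizon_start <- as.Date(horizon_start)
  horizon_end <- as.Date(horizon_end)
  if (horizon_start >= horizon_end) stop("horizon_start must precede horizon_end", call. = FALSE)
  structure(
    list(
      annual_transition_prob = annual_transition_prob,
      january_concentration = january_concentration,
      age_triggers = age_triggers,
      benefit_mix = benefit_mix,
      medicaid_seasonality_flat = isTRUE(medicaid_seasonality_flat),
      offbenefit_classes = offbenefit_classes,
      payor_pool_size = as.integer(payor_pool_size),
      pbm_pool_size = as.integer(pbm_pool_size),
      horizon_start = horizon_start,
      horizon_end = horizon_end
    ),
    class = "churn_config"
  )
}

#' Prospective DUR screening configuration
#'
#' @param history_window lookback in calendar days (boundary inclusive) over
#'   which a precipitating claim can pair with an incoming claim. Defaults to
#'   90 days: most maintenance prescriptions are dispensed for at most a
#'   90-day supply, so older fills are no longer active therapy.
#' @param require_active_supply if `TRUE` (default) the precipitating fill
#'   must still be on hand, i.e. `fill_date + days_supply >=` the incoming
#'   fill date.
#' @return an object of class `dur_config`.
#' @export
dur_config <- function(history_window = 90L, require_active_supply = TRUE) {
  history_window <- as.integer(history_window)
  if (is.na(history_window) || history_window <= 0) {
    stop("`history_window` must be a positive number of days", call. = FALSE)
  }
  structure(
    list(history_window = history_window,
         require_active_supply = isTRUE(require_active_supply)),
    class = "dur_config"
  )
}

#' Alert disposition configuration
#'
#' @param outcome_window days after the alert within which a resolving fill is
#'   sought (default 14). The window is half-open `(alert_date,
#'   alert_date + outcome_window]`: the rejected triggering fill itself does
#'   not count as its own resolution.
#' @param override_same_class if `TRUE`, a subsequent fill of any drug in the
#'   same therapeutic class counts as an override; by default an override
#'   requires a re-dispense of the same `drug_id`.
#' @return an object of class `outcome_config`.
#' @export
outcome_config <- function(outcome_window = 14L, override_same_class = FALSE) {
  outcome_window <- as.integer(outcome_window)
  if (is.na(outcome_window) || outcome_window <= 0) {
    stop("`outcome_window` must be a positive number of days", call. = FALSE)
  }
  structure(
    list(outcome_window = outcome_window,
         override_same_class = isTRUE(override_same_class)),
    class = "outcome_config"
  )
}
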