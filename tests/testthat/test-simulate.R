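no_churn <- function(...) {
  churn_config(annual_transition_prob = 0,
               age_triggers = c(`19` = 0, `26` = 0, `65` = 0), ...)
}

test_that("zero churn yields one span covering the whole horizon", {
  cfg <- no_churn()
  pop <- generate_population(1, cfg, seed = 7)
  expect_equal(nrow(pop$spans), 1)
  expect_equal(pop$spans$start_date, cfg$horizon_start)
  expect_equal(pop$spans$end_date, cfg$horizon_end)
})

test_that("certain January-concentrated churn puts a boundary on Jan 1 for every patient", {
  cfg <- churn_config(annual_transition_prob = 1, january_concentration = 1,
                      age_triggers = c(`19` = 0, `26` = 0, `65` = 0),
                      benefit_mix = c(MEDICAID = 0, EXCHANGE = 0,
                                      MEDICARE_D = 0, OTHER = 1))
  pop <- generate_population(1000, cfg, seed = 7)
  jan1 <- pop$spans |>
    dplyr::filter(format(start_date, "%m-%d") == "01-01") |>
    dplyr::distinct(true_patient_key)
  expect_equal(nrow(jan1), 1000)
})

test_that("empirical transition rate matches the configured annual probability", {
  p <- 0.3
  n <- 10000
  cfg <- churn_config(annual_transition_prob = p,
                      age_triggers = c(`19` = 0, `26` = 0, `65` = 0))
  pop <- generate_population(n, cfg, seed = 7)
  n_boundaries <- nrow(pop$spans) - n
  # patient-years: sum of calendar-year coverage fractions over the horizon
  yrs <- seq(as.integer(format(cfg$horizon_start, "%Y")),
             as.integer(format(cfg$horizon_end, "%Y")))
  frac <- sapply(yrs, function(y) {
    d0 <- max(as.Date(sprintf("%d-01-01", y)), cfg$horizon_start)
    d1 <- min(as.Date(sprintf("%d-12-31", y)), cfg$horizon_end)
    (as.numeric(d1 - d0) + 1) /
      (as.numeric(as.Date(sprintf("%d-12-31", y)) - as.Date(sprintf("%d-01-01", y))) + 1)
  })
  patient_years <- n * sum(frac)
  rate <- n_boundaries / patient_years
  tol <- 3 * sqrt(p * (1 - p) / patient_years)
  expect_lt(abs(rate - p), tol)
})

test_that("spans partition the horizon and change identifiers at every boundary", {
  for (seed in c(1, 22)) {
    cfg <- churn_config(annual_transition_prob = 0.5)
    pop <- generate_population(200, cfg, seed = seed)
    spans <- dplyr::arrange(pop$spans, true_patient_key, start_date)
    by_pat <- split(spans, spans$true_patient_key)
    for (sp in by_pat) {
      expect_equal(sp$start_date[1], cfg$horizon_start)
      expect_equal(sp$end_date[nrow(sp)], cfg$horizon_end)
      if (nrow(sp) > 1) {
        expect_equal(sp$start_date[-1], sp$end_date[-nrow(sp)] + 1)
        # payor transition at every boundary, fresh beneficiary id
        expect_true(all(sp$payor_id[-1] != sp$payor_id[-nrow(sp)]))
      }
    }
    expect_false(anyDuplicated(spans$beneficiary_id) > 0)
  }
})

test_that("population and claim generation are deterministic in the seed", {
  cfg <- churn_config()
  a <- generate_population(150, cfg, seed = 42)
  b <- generate_population(150, cfg, seed = 42)
  expect_identical(a$patients, b$patients)
  expect_identical(a$spans, b$spans)
  s1 <- simulate_claims(a, seed = 42)
  s2 <- simulate_claims(b, seed = 42)
  expect_identical(s1$claims, s2$claims)
  expect_identical(s1$truth, s2$truth)
  c_other <- generate_population(150, cfg, seed = 43)
  expect_false(identical(a$spans, c_other$spans))
})

test_that("ground-truth scan resolves hand-built interacting pairs", {
  # statin fill, then a macrolide 10 days later within the 30-day supply
  same_ids <- claim_rows(
    claim_row(1, "simvastatin", "2017-03-01", days_supply = 30),
    claim_row(2, "azithromycin", "2017-03-11")
  )
  truth <- ground_truth_alerts(same_ids, default_interaction_table())
  expect_equal(nrow(truth), 1)
  expect_equal(truth$triggering_claim_id, 2L)
  expect_equal(truth$precipitating_claim_id, 1L)
  expect_false(truth$crossover)

  crossed <- claim_rows(
    claim_row(1, "simvastatin", "2017-03-01", days_supply = 30,
              payor = "PAY1", ben = "B1"),
    claim_row(2, "azithromycin", "2017-03-11", payor = "PAY2", ben = "B2")
  )
  truth2 <- ground_truth_alerts(crossed, default_interaction_table())
  expect_equal(nrow(truth2), 1)
  expect_true(truth2$crossover)

  # outside the active supply: 100-day-old 30-day fill cannot precipitate
  stale <- claim_rows(
    claim_row(1, "simvastatin", "2017-03-01", days_supply = 30),
    claim_row(2, "azithromycin", "2017-06-09")
  )
  expect_equal(nrow(ground_truth_alerts(stale, default_interaction_table())), 0)
})

test_that("with no planted pairs and a non-interacting background the ledger is empty", {
  pop <- generate_population(300, churn_config(), seed = 5)
  sim <- simulate_claims(pop, ddi_plant_rate = 0, seed = 5)
  expect_equal(nrow(sim$truth), 0)
})

test_that("every claim is covered by an enrollment span of its true patient", {
  w <- demo_world(n_patients = 250, seed = 9)
  spans <- w$pop$spans
  covered <- w$claims |>
    dplyr::left_join(spans, by = dplyr::join_by(
      true_patient_key, between(x$fill_date, y$start_date, y$end_date)))
  expect_false(anyNA(covered$start_date))
  # non-cash claims carry exactly the identifiers of the active span
  non_cash <- covered[covered$payor_id.x != "CASH", ]
  expect_equal(non_cash$beneficiary_id.x, non_cash$beneficiary_id.y)
  expect_equal(non_cash$payor_id.x, non_cash$payor_id.y)
})

test_that("off-benefit fills use a cash identifier unique to patient and class", {
  cfg <- churn_config(offbenefit_classes = c(ED = 1))
  pop <- generate_population(400, cfg, seed = 3)
  sim <- simulate_claims(pop, ddi_plant_rate = 1,
                         plant_pair_classes = c("ED", "vasodilator"), seed = 3)
  ed <- sim$claims[sim$claims$therapeutic_class == "ED", ]
  expect_gt(nrow(ed), 0)
  expect_true(all(ed$payor_id == "CASH"))
  expect_equal(ed$beneficiary_id, paste0("CASH-", ed$true_patient_key, "-ED"))
})

test_that("demographic perturbation alters fields at the configured rate", {
  w <- demo_world(n_patients = 100, seed = 2)
  base <- w$claims

  expect_identical(perturb_demographics(base, 0, seed = 1), base)

  all_hit <- perturb_demographics(base, 1, seed = 1)
  changed <- all_hit$first_name != base$first_name |
    all_hit$last_name != base$last_name |
    all_hit$postal_code != base$postal_code
  expect_true(all(changed))
  expect_identical(all_hit$true_patient_key, base$true_patient_key)

  big <- dplyr::bind_rows(replicate(ceiling(10000 / nrow(base)), base,
                                    simplify = FALSE))[1:10000, ]
  rate <- 0.05
  pert <- perturb_demographics(big, rate, seed = 8)
  frac <- mean(pert$first_name != big$first_name |
                 pert$last_name != big$last_name |
                 pert$postal_code != big$postal_code)
  expected <- 1 - (1 - rate)^3
  tol <- 3 * sqrt(expected * (1 - expected) / nrow(big))
  expect_lt(abs(frac - expected), tol)
})

test_that("claim streams round-trip through the CSV contract", {
  w <- demo_world(n_patients = 40, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_claims(w$claims, f)
  back <- read_claims(f)
  expect_false("true_patient_key" %in% names(back))
  expect_equal(back$claim_id, w$claims$claim_id)
  expect_equal(back$fill_date, w$claims$fill_date)
  expect_equal(back$beneficiary_id, w$claims$beneficiary_id)
})

test_that("invalid configurations are rejected", {
  expect_error(churn_config(annual_transition_prob = 1.2), "probability")
  expect_error(churn_config(benefit_mix = c(MEDICAID = 0.5, EXCHANGE = 0.1,
                                            MEDICARE_D = 0.1, OTHER = 0.1)),
               "sum to 1")
  expect_error(dur_config(history_window = 0), "positive")
  expect_error(outcome_config(outcome_window = -1), "positive")
  expect_error(generate_population(0, churn_config()), "positive")
})
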