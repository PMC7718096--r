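test_that("market share is covered lives over the insured population", {
  expect_equal(market_share(49.7e6, 328e6, 0.915), 49.7e6 / (328e6 * 0.915))
  expect_equal(round_half_up(market_share(49.7e6, 328e6, 0.915), 4), 0.1656)
  expect_equal(market_share(5e6, 5e6, 1), 1)
  expect_equal(market_share(0, 328e6, 0.915), 0)
  expect_error(market_share(1e6, 0, 0.9), "positive")
})

test_that("the proportionality factor is 1/m - 1", {
  expect_equal(proportionality_factor(0.165), 5.06)
  expect_equal(proportionality_factor(1), 0)
  expect_equal(proportionality_factor(0.5), 1)
  expect_equal(proportionality_factor(0.165, digits = Inf), 1 / 0.165 - 1)
  expect_error(proportionality_factor(0), "share")
  expect_error(proportionality_factor(-0.1), "share")
})

test_that("projected crossover rates scale linearly with the factor", {
  expect_equal(round_half_up(project_crossover_rate(0.0098, 5.06), 3), 0.050)
  expect_equal(round_half_up(project_crossover_rate(0.019, 5.06), 3), 0.096)
  expect_equal(project_crossover_rate(0, 7), 0)
  expect_equal(project_crossover_rate(0.02, 5) / project_crossover_rate(0.01, 5), 2)
})

test_that("annualization divides by years and market share, with optional reweighting", {
  expect_equal(annualize_national_alerts(242646, 3, 0.165), 242646 / 3 / 0.165)
  expect_equal(annualize_national_alerts(0, 3, 0.165), 0)

  # national weights equal to the observed population shares: unweighted
  strata <- tibble::tibble(n_alerts = c(120, 60, 20),
                           pop_share = c(0.5, 0.3, 0.2),
                           weight = c(0.5, 0.3, 0.2))
  expect_equal(annualize_national_alerts(200, 2, 0.25, strata),
               annualize_national_alerts(200, 2, 0.25))
  # shifting national weight toward the highest-rate stratum raises the estimate
  skewed <- tibble::tibble(n_alerts = c(120, 60, 20),
                           pop_share = c(0.5, 0.3, 0.2),
                           weight = c(0.8, 0.1, 0.1))
  # stratum 1 rate: 120/0.5 = 240 per unit share, the highest of the three
  expect_gt(annualize_national_alerts(200, 2, 0.25, skewed),
            annualize_national_alerts(200, 2, 0.25))
  bad <- tibble::tibble(n_alerts = c(1, 1), pop_share = c(0.5, 0.5),
                        weight = c(0.6, 0.6))
  expect_error(annualize_national_alerts(200, 2, 0.25, bad), "sum to 1")
})

test_that("undetected and contraindicated projections follow the printed arithmetic", {
  expect_equal(round_half_up(undetected_alerts(458285, 0.0496)), 22731)
  expect_equal(undetected_alerts(458285, 0), 0)
  expect_equal(undetected_alerts(0, 0.05), 0)
  expect_equal(contraindicated_dispensings(22730, 0.165, 0.100), 6023)
  expect_equal(contraindicated_dispensings(100, 0, 0), 0)
  # only a + r matters, not the split
  expect_equal(contraindicated_dispensings(22730, 0.265, 0),
               contraindicated_dispensings(22730, 0.1, 0.165))
  expect_error(contraindicated_dispensings(10, 0.7, 0.4), "exceed")
})

test_that("the projection chain scales linearly in crossover volume", {
  base <- project_national(100000, 1000, study_years = 2,
                           abandonment_prop = 0.2, replacement_prop = 0.1,
                           market_share_override = 0.2)
  double <- project_national(100000, 2000, study_years = 2,
                             abandonment_prop = 0.2, replacement_prop = 0.1,
                             market_share_override = 0.2)
  expect_equal(double$undetected_annual, 2 * base$undetected_annual)
  expect_equal(base$projected_total_rate,
               base$observed_crossover_rate / base$market_share)
  expect_error(project_national(10, 20, abandonment_prop = 0.1,
                                replacement_prop = 0.1,
                                market_share_override = 0.2),
               "cannot exceed")
})

test_that("cohort selection matches a brute-force filter", {
  catalog <- default_drug_catalog()
  mk <- function(id, patient, drug, date, birth) {
    claim_row(id, drug, date, patient = patient, ben = paste0("B", patient),
              birth = birth)
  }
  cl <- claim_rows(
    # qualifies: two atorvastatin fills in 2017 at age 40
    mk(1, "P1", "atorvastatin", "2017-02-01", "1977-01-01"),
    mk(2, "P1", "atorvastatin", "2017-08-01", "1977-01-01"),
    # only one qualifying fill
    mk(3, "P2", "amlodipine", "2017-03-01", "1975-06-01"),
    # two fills but outside the age range
    mk(4, "P3", "atorvastatin", "2017-04-01", "1990-01-01"),
    mk(5, "P3", "atorvastatin", "2017-09-01", "1990-01-01"),
    # two fills but wrong year
    mk(6, "P4", "amlodipine", "2018-04-01", "1975-06-01"),
    mk(7, "P4", "amlodipine", "2018-09-01", "1975-06-01"),
    # mixed drugs both qualifying in 2017
    mk(8, "P5", "atorvastatin", "2017-01-15", "1972-12-01"),
    mk(9, "P5", "amlodipine", "2017-11-15", "1972-12-01")
  )
  map <- link_by_beneficiary(cl)
  cohort <- select_cohort(cl, map, index_year = 2017)
  linked <- dplyr::inner_join(cl, map[c("claim_id", "identity_key")], by = "claim_id")
  brute <- linked |>
    dplyr::filter(drug_id %in% c("atorvastatin", "amlodipine"),
                  format(fill_date, "%Y") == "2017",
                  age_at(birth_date, fill_date) >= 38,
                  age_at(birth_date, fill_date) <= 48) |>
    dplyr::count(identity_key) |>
    dplyr::filter(n >= 2)
  expect_setequal(cohort, brute$identity_key)
  expect_equal(length(cohort), 2)
})

test_that("attrition counts cohort identities absent from the target year", {
  cl <- claim_rows(
    claim_row(1, "atorvastatin", "2017-02-01", patient = "P1", ben = "BP1"),
    claim_row(2, "atorvastatin", "2018-02-01", patient = "P1", ben = "BP1"),
    claim_row(3, "atorvastatin", "2017-03-01", patient = "P2", ben = "BP2",
              birth = "1981-01-01"),
    claim_row(4, "metformin", "2018-05-01", patient = "P3", ben = "BP3",
              birth = "1982-01-01")
  )
  map <- link_by_beneficiary(cl)
  cohort <- c("PAY1|BP1", "PAY1|BP2")
  expect_equal(attrition(cohort, cl, map, 2018), 0.5)
  expect_equal(attrition(cohort, cl, map, 2017), 0)
  expect_error(attrition(character(), cl, map, 2018), "non-empty")
})

test_that("simulated attrition matches its binomial expectation", {
  # each of 4000 cohort members independently has 2018 claims with prob 0.7
  set.seed(202)
  n <- 4000
  ids <- sprintf("I%04d", seq_len(n))
  present <- stats::runif(n) < 0.7
  cl <- tibble::tibble(
    claim_id = seq_len(n),
    fill_date = as.Date(ifelse(present, "2018-06-01", "2017-06-01")),
    drug_id = "atorvastatin"
  )
  map <- tibble::tibble(claim_id = seq_len(n), identity_key = ids,
                        regime = "UPI")
  a <- attrition(ids, cl, map, 2018)
  tol <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(a - 0.3), tol)
})

test_that("the worked example chain reports internally consistent values", {
  wx <- worked_example_projection()
  expect_equal(wx$projection$proportionality_factor, wx$proportionality_factor)
  expect_equal(wx$crossover_pct,
               round_half_up(100 * wx$inputs$n_crossover / wx$inputs$n_alerts_total, 2))
  expect_equal(wx$abandoned_pct + wx$overridden_pct + wx$replaced_pct, 100)
})
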