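# Shared fixtures and independent oracles. The oracles deliberately use
# plain loops / exhaustive enumeration, separate from the package's
# vectorized-join implementations.

# build a claim row with sensible defaults, classes pulled from the catalog
claim_row <- function(claim_id, drug, fill_date, patient = "P1",
                      payor = "PAY1", ben = "B1", pbm = "PBM1",
                      benefit = "OTHER", first = "Anna", last = "Stoneberg",
                      birth = "1980-06-15", sex = "F", zip = "63101",
                      days_supply = NULL, catalog = default_drug_catalog()) {
  info <- catalog[catalog$drug_id == drug, ]
  stopifnot(nrow(info) == 1)
  tibble::tibble(
    claim_id = as.integer(claim_id),
    true_patient_key = patient,
    beneficiary_id = ben, payor_id = payor, pbm_id = pbm,
    benefit_type = benefit,
    first_name = first, last_name = last,
    birth_date = as.Date(birth), sex = sex, postal_code = zip,
    fill_date = as.Date(fill_date),
    drug_id = drug,
    therapeutic_class = info$therapeutic_class,
    condition_group = info$condition_group,
    days_supply = if (is.null(days_supply)) info$typical_days_supply else as.integer(days_supply),
    pharmacy_id = "PH001"
  )
}

claim_rows <- function(...) dplyr::bind_rows(...)

# quadratic screening oracle: explicit double loop within identity groups
oracle_alerts <- function(claims, map, interactions, config = dur_config()) {
  sym <- as.data.frame(symmetrize_interactions(interactions))
  sym <- sym[sym$severity == "SERIOUS", ]
  cl <- merge(as.data.frame(claims),
              as.data.frame(map[c("claim_id", "identity_key")]),
              by = "claim_id")
  out <- list()
  for (grp in split(cl, cl$identity_key)) {
    ng <- nrow(grp)
    if (ng < 2) next
    for (i in seq_len(ng)) {
      for (j in seq_len(ng)) {
        t <- grp[i, ]; p <- grp[j, ]
        earlier <- p$fill_date < t$fill_date ||
          (p$fill_date == t$fill_date && p$claim_id < t$claim_id)
        if (!earlier) next
        if (p$fill_date < t$fill_date - config$history_window) next
        if (config$require_active_supply &&
            p$fill_date + p$days_supply < t$fill_date) next
        hit <- any(sym$class_a == t$therapeutic_class &
                     sym$class_b == p$therapeutic_class)
        if (!hit) next
        out[[length(out) + 1]] <- data.frame(
          triggering_claim_id = t$claim_id,
          precipitating_claim_id = p$claim_id,
          crossover = t$payor_id != p$payor_id ||
            t$beneficiary_id != p$beneficiary_id
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(triggering_claim_id = integer(),
                          precipitating_claim_id = integer(),
                          crossover = logical()))
  }
  res <- dplyr::bind_rows(out)
  res[order(res$triggering_claim_id, res$precipitating_claim_id), ]
}

pair_key <- function(ledger) {
  paste(ledger$triggering_claim_id, ledger$precipitating_claim_id)
}

# pairwise demographic-matching oracle: test every claim pair against every
# pass, then take connected components by breadth-first search
oracle_upi_clusters <- function(claims, passes = upi_default_passes()) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  f <- data.frame(
    first_name = norm(claims$first_name),
    last_name = norm(claims$last_name),
    birth_date = as.character(claims$birth_date),
    sex = norm(claims$sex),
    postal_code = norm(claims$postal_code)
  )
  f$first_initial <- substr(f$first_name, 1, 1)
  n <- nrow(claims)
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      linked <- FALSE
      for (p in passes) {
        vi <- unlist(f[i, p]); vj <- unlist(f[j, p])
        if (all(!is.na(vi)) && all(vi != "") && all(vi == vj)) {
          linked <- TRUE
          break
        }
      }
      if (linked) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# exhaustive pairwise precision/recall over all claim pairs
oracle_pairwise_quality <- function(assignment, truth_keys) {
  n <- length(assignment)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_pred <- assignment[i] == assignment[j]
      same_true <- truth_keys[i] == truth_keys[j]
      tp <- tp + (same_pred && same_true)
      fp <- fp + (same_pred && !same_true)
      fn <- fn + (!same_pred && same_true)
    }
  }
  list(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1 else tp / (tp + fn))
}

# small simulated world used by several test files
demo_world <- function(n_patients = 300, seed = 11,
                       churn = churn_config(annual_transition_prob = 0.4),
                       ddi_plant_rate = 0.4, typo_rate = 0) {
  pop <- generate_population(n_patients, churn, seed = seed)
  sim <- simulate_claims(pop, ddi_plant_rate = ddi_plant_rate, seed = seed)
  claims <- perturb_demographics(sim$claims, typo_rate, seed = seed)
  list(pop = pop, claims = claims, truth = sim$truth)
}
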