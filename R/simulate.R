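# Synthetic population, enrollment and claims generator.
#
# The generator is the study bench for everything downstream: it emits claim
# streams with a known true patient behind every claim, and a ground-truth
# serious-DDI alert ledger computed by an exhaustive scan within true
# patients, so linkage and screening can be scored exactly.

# deterministic name pools (no RNG): syllable combinations
name_pool <- function(n, kind = c("first", "last")) {
  kind <- match.arg(kind)
  if (kind == "first") {
    a <- c("Al", "Ben", "Car", "Dan", "El", "Fran", "Gal", "Hel", "Ir", "Jul",
           "Kar", "Lor", "Mar", "Nor", "Ol", "Pat", "Quin", "Ros", "Sam", "Tan",
           "Ul", "Vic", "Wen", "Xan", "Yol", "Zar")
    b <- c("a", "o", "ia", "en", "on", "us", "ette", "ine", "er", "ey")
  } else {
    a <- c("And", "Berg", "Carl", "Dov", "Ell", "Fair", "Gold", "Hart", "Ing",
           "James", "Kirk", "Lind", "Mont", "New", "Oak", "Pem", "Quill", "Red",
           "Stone", "Tur", "Under", "Van", "West", "York", "Zim")
    b <- c("son", "berg", "field", "ton", "man", "stein", "wood", "lake",
           "hill", "ford", "well", "worth")
  }
  pool <- as.vector(outer(a, b, paste0))
  if (n > length(pool)) stop("name pool exhausted", call. = FALSE)
  pool[seq_len(n)]
}

#' Generate a synthetic patient population with enrollment histories
#'
#' Creates `n_patients` patients (demographics drawn from fixed pools) and a
#' set of non-overlapping enrollment spans per patient covering the whole
#' simulation horizon. Span boundaries are insurance transitions: annual payor
#' changes (optionally concentrated on January 1), and age-triggered changes
#' at the configured ages. Every transition assigns a fresh beneficiary
#' identifier and (usually) a new payor; each payor is served by a fixed PBM,
#' so a payor change may or may not also change the PBM. Patients aged 65 or
#' older are enrolled in Medicare Part D.
#'
#' @param n_patients number of patients (>= 1).
#' @param config a [churn_config()].
#' @param seed integer root seed; identical `(n_patients, config, seed)`
#'   reproduce identical output.
#' @return An object of class `ddi_population`: a list with tibbles
#'   `patients` (`true_patient_key`, `first_name`, `last_name`, `birth_date`,
#'   `sex`, `postal_code`) and `spans` (`true_patient_key`, `payor_id`,
#'   `pbm_id`, `beneficiary_id`, `benefit_type`, `start_date`, `end_date`).
#' @export
#' @examples
#' pop <- generate_population(50, churn_config(), seed = 1)
#' head(pop$spans)
generate_population <- function(n_patients, config = churn_config(), seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (!inherits(config, "churn_config")) {
    stop("`config` must be created with churn_config()", call. = FALSE)
  }
  withr::with_seed(stage_seed(seed, "population"),
                   generate_population_impl(n_patients, config))
}

generate_population_impl <- function(n, config) {
  h0 <- config$horizon_start
  h1 <- config$horizon_end
  pkey <- sprintf("P%06d", seq_len(n))

  firsts <- name_pool(200, "first")
  lasts <- name_pool(300, "last")
  zip_pool <- sprintf("%05d", sample(10000:99999, 500))
  patients <- tibble::tibble(
    true_patient_key = pkey,
    first_name = sample(firsts, n, replace = TRUE),
    last_name = sample(lasts, n, replace = TRUE),
    birth_date = h0 - (sample(5:85, n, replace = TRUE) * 365L +
                         sample(0:364, n, replace = TRUE)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    postal_code = sample(zip_pool, n, replace = TRUE)
  )

  mix <- config$benefit_mix
  benefit0 <- sample(names(mix), n, replace = TRUE, prob = mix)
  benefit0[age_at(patients$birth_date, h0) >= 65] <- "MEDICARE_D"

  # --- annual transitions, per calendar year overlapping the horizon -------
  yrs <- seq(as.integer(format(h0, "%Y")), as.integer(format(h1, "%Y")))
  year_grid <- tibble::tibble(year = yrs) |>
    dplyr::mutate(
      jan1 = as.Date(sprintf("%04d-01-01", .data$year)),
      dec31 = as.Date(sprintf("%04d-12-31", .data$year)),
      cov_start = pmax(.data$jan1, h0),
      cov_end = pmin(.data$dec31, h1),
      cov_days = as.numeric(.data$cov_end - .data$cov_start) + 1,
      frac = .data$cov_days / (as.numeric(.data$dec31 - .data$jan1) + 1),
      jan1_in = .data$jan1 >= h0 & .data$jan1 <= h1
    )

  grid <- tidyr::expand_grid(true_patient_key = pkey, year = yrs) |>
    dplyr::left_join(year_grid, by = "year") |>
    dplyr::mutate(benefit0 = rep(benefit0, each = length(yrs)))
  occurs <- stats::runif(nrow(grid)) < config$annual_transition_prob * grid$frac
  ann <- grid[occurs, , drop = FALSE]
  jan_eligible <- ann$jan1_in &
    !(config$medicaid_seasonality_flat & ann$benefit0 == "MEDICAID")
  on_jan <- jan_eligible & stats::runif(nrow(ann)) < config$january_concentration
  ann_date <- ann$cov_start + floor(stats::runif(nrow(ann)) * ann$cov_days)
  ann_date[on_jan] <- ann$jan1[on_jan]
  annual_bounds <- tibble::tibble(true_patient_key = ann$true_patient_key,
                                  date = ann_date)

  # --- age-triggered transitions ------------------------------------------
  age_bounds <- purrr::imap(config$age_triggers, function(p, a) {
    bd <- anniversary(patients$birth_date, as.integer(a))
    hit <- bd > h0 & bd <= h1 & stats::runif(n) < p
    tibble::tibble(true_patient_key = pkey[hit], date = bd[hit])
  })
  boundaries <- dplyr::bind_rows(annual_bounds, dplyr::bind_rows(age_bounds)) |>
    dplyr::filter(.data$date > h0, .data$date <= h1) |>
    dplyr::distinct()

  # --- assemble spans ------------------------------------------------------
  starts <- dplyr::bind_rows(
    tibble::tibble(true_patient_key = pkey, date = h0),
    boundaries
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$true_patient_key, .data$date)
  spans <- starts |>
    dplyr::group_by(.data$true_patient_key) |>
    dplyr::mutate(start_date = .data$date,
                  end_date = dplyr::lead(.data$date) - 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(end_date = dplyr::if_else(is.na(.data$end_date), h1, .data$end_date)) |>
    dplyr::select("true_patient_key", "start_date", "end_date")

  ns <- nrow(spans)
  payor_idx <- sample.int(config$payor_pool_size, ns, replace = TRUE)
  # a transition nearly always means a different payor; redraw collisions
  repeat {
    same <- c(FALSE, payor_idx[-1] == payor_idx[-ns] &
                spans$true_patient_key[-1] == spans$true_patient_key[-ns])
    if (!any(same)) break
    payor_idx[same] <- sample.int(config$payor_pool_size, sum(same), replace = TRUE)
  }
  pbm_of_payor <- ((seq_len(config$payor_pool_size) - 1L) %% config$pbm_pool_size) + 1L
  spans$payor_id <- sprintf("PAY%03d", payor_idx)
  spans$pbm_id <- sprintf("PBM%d", pbm_of_payor[payor_idx])
  spans$beneficiary_id <- sprintf("B%09d", sample.int(999999999L, ns))
  spans <- spans |>
    dplyr::left_join(tibble::tibble(true_patient_key = pkey, benefit0 = benefit0,
                                    birth_date = patients$birth_date),
                     by = "true_patient_key") |>
    dplyr::mutate(
      benefit_type = dplyr::if_else(age_at(.data$birth_date, .data$start_date) >= 65,
                                    "MEDICARE_D", .data$benefit0)
    ) |>
    dplyr::select("true_patient_key", "payor_id", "pbm_id", "beneficiary_id",
                  "benefit_type", "start_date", "end_date")

  structure(list(patients = patients, spans = spans, config = config),
            class = "ddi_population")
}

#' Simulate pharmacy claims with planted serious-DDI pairs
#'
#' Generates a claim stream for a population from [generate_population()]:
#' a background of non-interacting chronic-therapy fills, plus, for a random
#' subset of patients, one planted pair of fills whose therapeutic classes
#' form a serious interaction and whose timing satisfies the screening
#' predicate (within the history window, precipitating supply still active).
#' Each claim carries the insurance identifiers of the enrollment span active
#' on its fill date; fills of classes in `config$offbenefit_classes` are,
#' with the configured probability, adjudicated under an alternate
#' cash/coupon identifier unique to the (patient, class) pair.
#'
#' The returned ground-truth ledger is computed by [ground_truth_alerts()]:
#' an exhaustive within-patient pair scan, so it also captures any incidental
#' interacting pairs beyond the planted ones.
#'
#' @param population a `ddi_population`.
#' @param catalog drug catalog tibble; see [default_drug_catalog()].
#' @param interactions interaction table tibble; see
#'   [default_interaction_table()].
#' @param ddi_plant_rate per-patient probability of receiving one planted
#'   interacting pair.
#' @param fills_per_year mean background fills per patient-year (Poisson).
#' @param background_classes therapeutic classes eligible for background
#'   fills. The default set is mutually non-interacting, so all serious-DDI
#'   exposure is controlled by `ddi_plant_rate`.
#' @param crossover_share optional probability in `[0, 1]`. When supplied,
#'   planted pairs are placed on patients with at least two enrollment spans
#'   and are forced to straddle an identifier change with exactly this
#'   probability (otherwise both fills sit inside one span), giving a known
#'   true cross-identifier share for calibration experiments. When `NULL`
#'   (default), pair timing is natural and crossover status emerges from the
#'   churn process.
#' @param plant_pair_classes optional character vector restricting planted
#'   interaction pairs to those whose two classes both belong to this set.
#' @param dur a [dur_config()]; defines the screening predicate used for the
#'   ground-truth ledger.
#' @param seed integer root seed.
#' @return An object of class `ddi_claims`: list with `claims` (one row per
#'   adjudicated fill, including the hidden `true_patient_key`) and `truth`
#'   (ground-truth alert ledger: `triggering_claim_id`,
#'   `precipitating_claim_id`, `crossover`).
#' @export
simulate_claims <- function(population,
                            catalog = default_drug_catalog(),
                            interactions = default_interaction_table(),
                            ddi_plant_rate = 0.15,
                            fills_per_year = 3,
                            background_classes = c("statin", "ccb", "ace_inhibitor",
                                                   "biguanide", "thyroid_hormone",
                                                   "ssri"),
                            crossover_share = NULL,
                            plant_pair_classes = NULL,
                            dur = dur_config(),
                            seed = 1L) {
  if (!inherits(population, "ddi_population")) {
    stop("`population` must come from generate_population()", call. = FALSE)
  }
  validate_catalog(catalog)
  if (nrow(interactions) == 0) stop("interaction table must be non-empty", call. = FALSE)
  check_prob(ddi_plant_rate, "ddi_plant_rate")
  if (!is.null(crossover_share)) check_prob(crossover_share, "crossover_share")
  withr::with_seed(
    stage_seed(seed, "claims"),
    simulate_claims_impl(population, catalog, interactions, ddi_plant_rate,
                         fills_per_year, background_classes, crossover_share,
                         plant_pair_classes, dur)
  )
}

simulate_claims_impl <- function(population, catalog, interactions,
                                 ddi_plant_rate, fills_per_year,
                                 background_classes, crossover_share,
                                 plant_pair_classes, dur) {
  config <- population$config
  h0 <- config$horizon_start
  h1 <- config$horizon_end
  horizon_days <- as.numeric(h1 - h0) + 1
  patients <- population$patients
  spans <- population$spans
  n <- nrow(patients)
  pkey <- patients$true_patient_key

  # --- background stream ---------------------------------------------------
  bg_cat <- catalog[catalog$therapeutic_class %in% background_classes, , drop = FALSE]
  if (length(background_classes) > 0 && nrow(bg_cat) == 0) {
    stop("no catalog drugs in `background_classes`", call. = FALSE)
  }
  bg <- NULL
  if (nrow(bg_cat) > 0 && fills_per_year > 0) {
    n_bg <- stats::rpois(n, fills_per_year * horizon_days / 365.25)
    bg <- tibble::tibble(
      true_patient_key = rep(pkey, n_bg),
      drug_id = sample(bg_cat$drug_id, sum(n_bg), replace = TRUE),
      fill_date = h0 + floor(stats::runif(sum(n_bg)) * horizon_days)
    )
  }

  # --- planted interacting pairs ------------------------------------------
  pairs_tbl <- interactions
  if (!is.null(plant_pair_classes)) {
    pairs_tbl <- pairs_tbl[pairs_tbl$class_a %in% plant_pair_classes &
                             pairs_tbl$class_b %in% plant_pair_classes, , drop = FALSE]
    if (nrow(pairs_tbl) == 0) stop("no interaction pairs within `plant_pair_classes`", call. = FALSE)
  }
  w <- pairs_tbl$plant_weight %||% rep(1, nrow(pairs_tbl))
  if (is.null(pairs_tbl[["plant_weight"]])) w <- rep(1, nrow(pairs_tbl))

  spans_by_patient <- split(spans, spans$true_patient_key)
  n_spans_per <- vapply(spans_by_patient, nrow, integer(1))[pkey]

  if (is.null(crossover_share)) {
    planted_keys <- pkey[stats::runif(n) < ddi_plant_rate]
  } else {
    eligible <- pkey[n_spans_per >= 2]
    if (length(eligible) == 0) stop("crossover_share requires patients with >= 2 spans", call. = FALSE)
    planted_keys <- eligible[stats::runif(length(eligible)) < ddi_plant_rate]
  }

  planted <- NULL
  if (length(planted_keys) > 0) {
    rows <- sample.int(nrow(pairs_tbl), length(planted_keys), replace = TRUE, prob = w)
    drugs_of <- split(catalog$drug_id, catalog$therapeutic_class)
    ds_of <- stats::setNames(catalog$typical_days_supply, catalog$drug_id)
    pick_drug <- function(cls) {
      d <- drugs_of[[cls]]
      if (length(d) == 1) d else sample(d, 1)
    }
    one_pair <- function(i) {
      key <- planted_keys[i]
      cls <- c(pairs_tbl$class_a[rows[i]], pairs_tbl$class_b[rows[i]])
      if (is.null(crossover_share)) cls <- sample(cls) # random orientation
      drug_a <- pick_drug(cls[1]) # precipitating
      drug_b <- pick_drug(cls[2]) # triggering
      ds_a <- ds_of[[drug_a]]
      sp <- spans_by_patient[[key]]
      if (is.null(crossover_share)) {
        gap <- sample.int(min(ds_a, dur$history_window, 75L), 1)
        t1 <- h0 + floor(stats::runif(1) * (horizon_days - gap - 1))
        t2 <- t1 + gap
      } else if (stats::runif(1) < crossover_share) {
        # force the pair to straddle an identifier change
        bnds <- sp$start_date[-1]
        ok <- bnds >= h0 + 6 & bnds <= h1 - 5
        b <- if (any(ok)) sample(rep(bnds[ok], 2), 1) else sample(rep(bnds, 2), 1)
        t1 <- max(b - sample.int(5, 1), h0)
        t2 <- min(b + sample.int(5, 1) - 1L, h1)
      } else {
        # keep both fills inside one enrollment span
        lens <- as.numeric(sp$end_date - sp$start_date) + 1
        cand <- which(lens >= 12)
        j <- if (length(cand) > 0) sample(rep(cand, 2), 1) else which.max(lens)
        t1 <- sp$start_date[j] + floor(stats::runif(1) * max(lens[j] - 10, 1))
        t2 <- min(t1 + sample.int(9, 1), sp$end_date[j])
        if (t2 <= t1) t2 <- t1 + 1 # degenerate tiny span; may cross, vanishingly rare
      }
      tibble::tibble(true_patient_key = key,
                     drug_id = c(drug_a, drug_b),
                     fill_date = c(t1, t2))
    }
    planted <- dplyr::bind_rows(lapply(seq_along(planted_keys), one_pair))
  }

  claims <- dplyr::bind_rows(bg, planted)
  if (nrow(claims) == 0) {
    empty_claims <- empty_claim_stream()
    return(structure(list(claims = empty_claims, truth = empty_truth()),
                     class = "ddi_claims"))
  }

  claims <- claims |>
    dplyr::left_join(catalog, by = "drug_id") |>
    dplyr::rename(days_supply = "typical_days_supply") |>
    dplyr::left_join(
      spans,
      by = dplyr::join_by("true_patient_key",
                          dplyr::between(x$fill_date, y$start_date, y$end_date))
    )
  if (anyNA(claims$beneficiary_id)) {
    stop("internal error: claim fill date outside all enrollment spans", call. = FALSE)
  }

  # off-benefit (cash/coupon) substitution for excluded classes
  ob <- config$offbenefit_classes
  if (length(ob) > 0) {
    for (cls in names(ob)) {
      hit <- claims$therapeutic_class == cls & stats::runif(nrow(claims)) < ob[[cls]]
      claims$payor_id[hit] <- "CASH"
      claims$pbm_id[hit] <- "CASH"
      claims$beneficiary_id[hit] <- paste0("CASH-", claims$true_patient_key[hit], "-", cls)
    }
  }

  claims <- claims |>
    dplyr::left_join(patients, by = "true_patient_key") |>
    dplyr::arrange(.data$fill_date, .data$true_patient_key, .data$drug_id) |>
    dplyr::mutate(
      claim_id = dplyr::row_number(),
      pharmacy_id = sample(sprintf("PH%03d", 1:50), dplyr::n(), replace = TRUE)
    ) |>
    dplyr::select("claim_id", "true_patient_key", "beneficiary_id", "payor_id",
                  "pbm_id", "benefit_type", "first_name", "last_name",
                  "birth_date", "sex", "postal_code", "fill_date", "drug_id",
                  "therapeutic_class", "condition_group", "days_supply",
                  "pharmacy_id")

  truth <- ground_truth_alerts(claims, interactions, dur)
  structure(list(claims = claims, truth = truth), class = "ddi_claims")
}

empty_claim_stream <- function() {
  tibble::tibble(
    claim_id = integer(), true_patient_key = character(),
    beneficiary_id = character(), payor_id = character(), pbm_id = character(),
    benefit_type = character(), first_name = character(), last_name = character(),
    birth_date = as.Date(character()), sex = character(), postal_code = character(),
    fill_date = as.Date(character()), drug_id = character(),
    therapeutic_class = character(), condition_group = character(),
    days_supply = integer(), pharmacy_id = character()
  )
}

empty_truth <- function() {
  tibble::tibble(triggering_claim_id = integer(),
                 precipitating_claim_id = integer(),
                 crossover = logical())
}

#' Ground-truth serious-DDI alert ledger by exhaustive within-patient scan
#'
#' Enumerates every ordered pair of claims belonging to the same true patient
#' and keeps pairs satisfying the screening predicate: the precipitating fill
#' strictly precedes the triggering fill (ties broken by smaller claim id),
#' lies within the history window, its supply is still active when required,
#' and the two therapeutic classes form a SERIOUS interaction. The crossover
#' flag is true when the two fills carry different `(payor_id,
#' beneficiary_id)` identifiers. This is the oracle that a perfect-identity
#' screening run must reproduce.
#'
#' @param claims a claim stream tibble carrying `true_patient_key`.
#' @param interactions interaction table (one orientation per pair is enough).
#' @param dur a [dur_config()].
#' @return tibble `triggering_claim_id`, `precipitating_claim_id`,
#'   `crossover`, ordered by triggering then precipitating claim id.
#' @export
ground_truth_alerts <- function(claims, interactions, dur = dur_config()) {
  if (nrow(claims) == 0) return(empty_truth())
  check_cols(claims, c("claim_id", "true_patient_key", "fill_date",
                       "therapeutic_class", "days_supply", "payor_id",
                       "beneficiary_id"), "claims")
  sym <- symmetrize_interactions(interactions)
  sym <- sym[sym$severity == "SERIOUS", c("class_a", "class_b")]
  trig <- claims |>
    dplyr::select(true_patient_key = "true_patient_key", t_id = "claim_id",
                  t_date = "fill_date", t_class = "therapeutic_class",
                  t_payor = "payor_id", t_ben = "beneficiary_id")
  prec <- claims |>
    dplyr::select(true_patient_key = "true_patient_key", p_id = "claim_id",
                  p_date = "fill_date", p_class = "therapeutic_class",
                  p_ds = "days_supply", p_payor = "payor_id",
                  p_ben = "beneficiary_id")
  pairs <- dplyr::inner_join(trig, prec, by = "true_patient_key",
                             relationship = "many-to-many") |>
    dplyr::filter(
      .data$p_date < .data$t_date |
        (.data$p_date == .data$t_date & .data$p_id < .data$t_id),
      .data$p_date >= .data$t_date - dur$history_window
    )
  if (dur$require_active_supply) {
    pairs <- dplyr::filter(pairs, .data$p_date + .data$p_ds >= .data$t_date)
  }
  pairs |>
    dplyr::inner_join(sym, by = c(t_class = "class_a", p_class = "class_b")) |>
    dplyr::transmute(
      triggering_claim_id = .data$t_id,
      precipitating_claim_id = .data$p_id,
      crossover = .data$t_payor != .data$p_payor | .data$t_ben != .data$p_ben
    ) |>
    dplyr::arrange(.data$triggering_claim_id, .data$precipitating_claim_id)
}

#' Inject demographic transcription errors into a claim stream
#'
#' Independently corrupts each of `first_name`, `last_name` and `postal_code`
#' on each claim with probability `typo_rate`: a single-character
#' substitution or adjacent transposition for names, a fresh random ZIP for
#' postal codes. `true_patient_key` is untouched (it is the hidden truth).
#'
#' @param claims claim stream tibble.
#' @param typo_rate per-field corruption probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the claim stream with corrupted demographic fields.
#' @export
perturb_demographics <- function(claims, typo_rate, seed = 1L) {
  check_prob(typo_rate, "typo_rate")
  if (typo_rate == 0 || nrow(claims) == 0) return(claims)
  withr::with_seed(stage_seed(seed, "perturb"), {
    for (field in c("first_name", "last_name", "postal_code")) {
      hit <- stats::runif(nrow(claims)) < typo_rate
      if (any(hit)) {
        claims[[field]][hit] <- vapply(claims[[field]][hit], corrupt_string, "",
                                       postal = field == "postal_code")
      }
    }
    claims
  })
}

corrupt_string <- function(x, postal = FALSE) {
  if (postal) {
    repeat {
      y <- sprintf("%05d", sample(0:99999, 1))
      if (y != x) return(y)
    }
  }
  chars <- strsplit(x, "")[[1]]
  nc <- length(chars)
  op <- if (nc >= 2 && stats::runif(1) < 0.5) "transpose" else "substitute"
  if (op == "transpose") {
    i <- sample.int(nc - 1, 1)
    if (chars[i] != chars[i + 1]) {
      tmp <- chars[i]; chars[i] <- chars[i + 1]; chars[i + 1] <- tmp
      return(paste(chars, collapse = ""))
    }
    # fall through to substitution when adjacent chars are equal
  }
  i <- sample.int(nc, 1)
  repeat {
    new <- sample(letters, 1)
    if (!identical(tolower(chars[i]), new)) break
  }
  chars[i] <- new
  paste(chars, collapse = "")
}

#' Read and write claim streams as CSV
#'
#' The on-disk schema is the external contract (no `true_patient_key`):
#' `claim_id, beneficiary_id, payor_id, pbm_id, benefit_type, first_name,
#' last_name, birth_date, sex, postal_code, fill_date, drug_id,
#' therapeutic_class, condition_group, days_supply, pharmacy_id`, dates in
#' ISO-8601.
#'
#' @param claims claim stream tibble.
#' @param path file path.
#' @param keep_truth if `TRUE`, retain `true_patient_key` in the file
#'   (useful for evaluation fixtures).
#' @return `read_claims()` returns a tibble; `write_claims()` returns `path`
#'   invisibly.
#' @export
write_claims <- function(claims, path, keep_truth = FALSE) {
  out <- claims
  if (!keep_truth) out$true_patient_key <- NULL
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_claims
#' @export
read_claims <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    claim_id = readr::col_integer(),
    birth_date = readr::col_date(),
    fill_date = readr::col_date(),
    days_supply = readr::col_integer(),
    .default = readr::col_character()
  ))
}
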