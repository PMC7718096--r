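# Identity linkage: assign claims to patient identities under two regimes.
#
# BENEFICIARY: the identity is the payor-assigned member id, scoped to the
# payor; a record from a new payor is a new patient.
# UPI: deterministic demographic matching; claims sharing a key in any
# configured pass are merged transitively into one identity.

#' Default demographic matching passes
#'
#' Each pass is a character vector of matching fields evaluated after
#' normalization (case-folded, punctuation and whitespace stripped).
#' `first_initial` is the first character of the normalized first name.
#' Pass 1: full name + birth date + sex. Pass 2: first initial + last name +
#' birth date + postal code (tolerates first-name variants and sex coding
#' errors when the address corroborates).
#'
#' @return list of character vectors of field names.
#' @export
upi_default_passes <- function() {
  list(
    c("first_name", "last_name", "birth_date", "sex"),
    c("first_initial", "last_name", "birth_date", "postal_code")
  )
}

normalize_demo <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Link claims by health-insurance beneficiary identifier
#'
#' The identity of a claim is the `(payor_id, beneficiary_id)` pair. No
#' linkage occurs across payors: a record from a new payor is a new patient.
#'
#' @param claims claim stream tibble with `claim_id`, `payor_id`,
#'   `beneficiary_id`.
#' @return a linkage map tibble: `claim_id`, `identity_key`, `regime`
#'   (`"BENEFICIARY"`).
#' @export
link_by_beneficiary <- function(claims) {
  if (nrow(claims) == 0) stop("`claims` must be non-empty", call. = FALSE)
  check_cols(claims, c("claim_id", "payor_id", "beneficiary_id"), "claims")
  bad <- is.na(claims$beneficiary_id) | claims$beneficiary_id == ""
  if (any(bad)) {
    stop(sprintf("%d claim(s) have a missing beneficiary_id", sum(bad)), call. = FALSE)
  }
  tibble::tibble(
    claim_id = claims$claim_id,
    identity_key = paste(claims$payor_id, claims$beneficiary_id, sep = "|"),
    regime = "BENEFICIARY"
  )
}

#' Link claims to a unique patient identifier by deterministic matching
#'
#' Builds one matching key per pass and per claim, then computes the
#' transitive closure: claims sharing a key in any pass end up in the same
#' identity, as do claims connected through chains of such matches. The
#' identity key is the minimum claim id in the connected component, so the
#' assignment is stable across runs on identical input. Records with a
#' missing field in a pass simply do not participate in that pass; a record
#' with all demographic fields missing is reported and left a singleton.
#'
#' @param claims claim stream tibble with demographic columns.
#' @param passes list of field-name vectors; see [upi_default_passes()].
#' @return a linkage map tibble: `claim_id`, `identity_key`, `regime`
#'   (`"UPI"`).
#' @export
link_by_upi <- function(claims, passes = upi_default_passes()) {
  if (nrow(claims) == 0) stop("`claims` must be non-empty", call. = FALSE)
  if (length(passes) == 0) stop("`passes` must be non-empty", call. = FALSE)
  check_cols(claims, c("claim_id", "first_name", "last_name", "birth_date",
                       "sex", "postal_code"), "claims")

  fields <- tibble::tibble(
    first_name = normalize_demo(claims$first_name),
    last_name = normalize_demo(claims$last_name),
    birth_date = as.character(claims$birth_date),
    sex = normalize_demo(claims$sex),
    postal_code = normalize_demo(claims$postal_code)
  )
  fields$first_initial <- substr(fields$first_name, 1, 1)
  blank <- function(v) is.na(v) | v == ""
  all_missing <- blank(fields$first_name) & blank(fields$last_name) &
    blank(fields$birth_date) & blank(fields$postal_code)
  if (any(all_missing)) {
    message(sprintf("%d claim(s) have no usable demographics; assigned singleton identities",
                    sum(all_missing)))
  }

  keys <- lapply(passes, function(p) {
    miss <- setdiff(p, names(fields))
    if (length(miss) > 0) stop(sprintf("unknown pass field(s): %s", paste(miss, collapse = ", ")),
                               call. = FALSE)
    parts <- fields[p]
    k <- do.call(paste, c(parts, sep = "\r"))
    usable <- !Reduce(`|`, lapply(parts, blank))
    # records unusable in this pass get a unique key: no merging through them
    k[!usable] <- paste0("\r__solo__", claims$claim_id[!usable])
    k
  })

  # transitive closure by iterated minimum-label propagation over pass keys;
  # labels are ranks of claim_id, so the component label is the minimum
  # claim id regardless of the id type
  rk <- rank(claims$claim_id, ties.method = "first")
  lab <- as.integer(rk)
  repeat {
    old <- lab
    for (k in keys) {
      lab <- stats::ave(lab, k, FUN = min)
    }
    if (identical(lab, old)) break
  }
  ids <- claims$claim_id[match(lab, rk)]
  tibble::tibble(
    claim_id = claims$claim_id,
    identity_key = paste0("U", ids),
    regime = "UPI"
  )
}

#' Score a linkage map against the planted truth
#'
#' Pairwise precision and recall over co-assignment of claim pairs: of all
#' claim pairs placed in one identity, how many truly belong to one patient
#' (precision); of all claim pairs truly belonging to one patient, how many
#' were co-assigned (recall). Conventions: with no predicted (resp. true)
#' pairs, precision (resp. recall) is 1. Entity-level errors are also
#' counted: `n_splits` is the number of true patients fragmented across more
#' than one identity, `n_merges` the number of identities spanning more than
#' one true patient.
#'
#' @param map linkage map from [link_by_beneficiary()] or [link_by_upi()].
#' @param truth tibble with `claim_id`, `true_patient_key` covering every
#'   mapped claim.
#' @return object of class `linkage_quality`: list with `precision`,
#'   `recall`, `n_splits`, `n_merges`.
#' @export
linkage_quality <- function(map, truth) {
  check_cols(map, c("claim_id", "identity_key"), "linkage map")
  check_cols(truth, c("claim_id", "true_patient_key"), "truth")
  joined <- dplyr::inner_join(map, truth, by = "claim_id")
  if (nrow(joined) < nrow(map)) {
    stop("`truth` must cover every claim in the linkage map", call. = FALSE)
  }
  cell <- dplyr::count(joined, .data$identity_key, .data$true_patient_key)
  by_id <- dplyr::count(joined, .data$identity_key)
  by_truth <- dplyr::count(joined, .data$true_patient_key)
  tp <- sum(choose2(cell$n))
  pred <- sum(choose2(by_id$n))
  pos <- sum(choose2(by_truth$n))
  structure(
    list(
      precision = if (pred == 0) 1 else tp / pred,
      recall = if (pos == 0) 1 else tp / pos,
      n_splits = sum(dplyr::count(cell, .data$true_patient_key)$n > 1),
      n_merges = sum(dplyr::count(cell, .data$identity_key)$n > 1)
    ),
    class = "linkage_quality"
  )
}

#' @export
print.linkage_quality <- function(x, ...) {
  cat(sprintf(
    "Linkage quality: precision %.4f, recall %.4f, %d split patient(s), %d merged identit(ies)\n",
    x$precision, x$recall, x$n_splits, x$n_merges))
  invisible(x)
}

#' Write a linkage map as CSV
#'
#' @param map linkage map tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_linkage_map <- function(map, path) {
  readr::write_csv(map, path)
  invisible(path)
}
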