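test_that("beneficiary linkage keys on the (payor, beneficiary) pair", {
  cl <- claim_rows(
    claim_row(1, "atorvastatin", "2017-01-10", payor = "PAY1", ben = "B1"),
    claim_row(2, "atorvastatin", "2017-02-10", payor = "PAY1", ben = "B1"),
    claim_row(3, "atorvastatin", "2017-03-10", payor = "PAY2", ben = "B2")
  )
  map <- link_by_beneficiary(cl)
  expect_equal(dplyr::n_distinct(map$identity_key), 2)
  expect_equal(map$identity_key[1], map$identity_key[2])
  expect_false(map$identity_key[1] == map$identity_key[3])

  # k distinct (payor, beneficiary) pairs -> k identities
  set.seed(31)
  pairs <- expand.grid(payor = paste0("PAY", 1:5), ben = paste0("B", 1:4),
                       stringsAsFactors = FALSE)
  idx <- sample(nrow(pairs), 60, replace = TRUE)
  cl2 <- dplyr::bind_rows(lapply(seq_along(idx), function(i) {
    claim_row(i, "atorvastatin", "2017-01-01",
              payor = pairs$payor[idx[i]], ben = pairs$ben[idx[i]])
  }))
  map2 <- link_by_beneficiary(cl2)
  expect_equal(dplyr::n_distinct(map2$identity_key),
               dplyr::n_distinct(paste(cl2$payor_id, cl2$beneficiary_id)))

  expect_error(link_by_beneficiary(dplyr::mutate(cl, beneficiary_id = NA_character_)),
               "missing beneficiary_id")
})

test_that("UPI matching merges across payors and tolerates case and punctuation", {
  cl <- claim_rows(
    claim_row(1, "atorvastatin", "2017-01-10", payor = "PAY1", ben = "B1",
              first = "Anna", last = "Stoneberg"),
    claim_row(2, "atorvastatin", "2017-02-10", payor = "PAY2", ben = "B2",
              first = "ANNA", last = "stone-berg")
  )
  map <- link_by_upi(cl)
  expect_equal(dplyr::n_distinct(map$identity_key), 1)
  # identity key is the minimum claim id in the component
  expect_equal(unique(map$identity_key), "U1")
})

test_that("distinct demographics stay distinct identities", {
  cl <- claim_rows(
    claim_row(1, "atorvastatin", "2017-01-10", first = "Anna", last = "Stoneberg"),
    claim_row(2, "atorvastatin", "2017-02-10", first = "Marcus", last = "Redford",
              birth = "1955-02-02", zip = "10001")
  )
  map <- link_by_upi(cl)
  expect_equal(dplyr::n_distinct(map$identity_key), 2)
})

test_that("a second pass can bridge a first-name typo via initial and postal code", {
  cl <- claim_rows(
    claim_row(1, "atorvastatin", "2017-01-10", first = "Anna"),
    claim_row(2, "atorvastatin", "2017-02-10", first = "Annq")
  )
  both <- link_by_upi(cl, upi_default_passes())
  expect_equal(dplyr::n_distinct(both$identity_key), 1)
  only_exact <- link_by_upi(cl, upi_default_passes()[1])
  expect_equal(dplyr::n_distinct(only_exact$identity_key), 2)
})

test_that("UPI linkage equals the pairwise brute-force evaluation on a perturbed stream", {
  w <- demo_world(n_patients = 60, seed = 13, typo_rate = 0.05)
  cl <- w$claims
  map <- link_by_upi(cl)
  comp <- oracle_upi_clusters(cl)
  # identical partitions of the claim set
  expect_equal(dplyr::n_distinct(map$identity_key), dplyr::n_distinct(comp))
  expect_true(all(tapply(comp, map$identity_key, dplyr::n_distinct) == 1))

  q <- linkage_quality(map, cl[c("claim_id", "true_patient_key")])
  oq <- oracle_pairwise_quality(comp, cl$true_patient_key)
  expect_equal(q$precision, oq$precision)
  expect_equal(q$recall, oq$recall)
})

test_that("with clean demographics the UPI regime recovers the truth perfectly", {
  w <- demo_world(n_patients = 400, seed = 17, typo_rate = 0)
  q <- linkage_quality(link_by_upi(w$claims),
                       w$claims[c("claim_id", "true_patient_key")])
  expect_equal(q$precision, 1)
  expect_equal(q$recall, 1)
  expect_equal(q$n_splits, 0)
  expect_equal(q$n_merges, 0)
})

test_that("adding a matching pass never decreases recall", {
  for (seed in c(3, 14)) {
    w <- demo_world(n_patients = 80, seed = seed, typo_rate = 0.08)
    truth <- w$claims[c("claim_id", "true_patient_key")]
    r1 <- linkage_quality(link_by_upi(w$claims, upi_default_passes()[1]), truth)$recall
    r2 <- linkage_quality(link_by_upi(w$claims, upi_default_passes()), truth)$recall
    expect_gte(r2, r1)
  }
})

test_that("linkage quality matches exhaustive pair enumeration on small instances", {
  # perfect map
  cl <- claim_rows(
    claim_row(1, "atorvastatin", "2017-01-10"),
    claim_row(2, "atorvastatin", "2017-02-10")
  )
  perfect <- tibble::tibble(claim_id = 1:2, identity_key = "I1", regime = "UPI")
  q <- linkage_quality(perfect, cl[c("claim_id", "true_patient_key")])
  expect_equal(unclass(q)[c("precision", "recall", "n_splits", "n_merges")],
               list(precision = 1, recall = 1, n_splits = 0, n_merges = 0))

  # all singletons on a 2-claim patient: nothing predicted, truth pairs missed
  single <- tibble::tibble(claim_id = 1:2, identity_key = c("I1", "I2"),
                           regime = "UPI")
  q2 <- linkage_quality(single, cl[c("claim_id", "true_patient_key")])
  expect_equal(q2$precision, 1)
  expect_equal(q2$recall, 0)
  expect_equal(q2$n_splits, 1)

  # random 6-claim instances vs exhaustive enumeration over all 15 pairs
  set.seed(99)
  for (rep in 1:5) {
    truth_keys <- sample(c("PA", "PB", "PC"), 6, replace = TRUE)
    assignment <- sample(c("I1", "I2", "I3"), 6, replace = TRUE)
    map <- tibble::tibble(claim_id = 1:6, identity_key = assignment,
                          regime = "UPI")
    truth <- tibble::tibble(claim_id = 1:6, true_patient_key = truth_keys)
    q <- linkage_quality(map, truth)
    oq <- oracle_pairwise_quality(assignment, truth_keys)
    expect_equal(q$precision, oq$precision)
    expect_equal(q$recall, oq$recall)
  }
})

test_that("claims with unusable demographics become logged singletons", {
  cl <- claim_rows(
    claim_row(1, "atorvastatin", "2017-01-10"),
    claim_row(2, "atorvastatin", "2017-02-10")
  )
  cl$first_name[2] <- NA
  cl$last_name[2] <- NA
  cl$birth_date[2] <- NA
  cl$postal_code[2] <- NA
  expect_message(map <- link_by_upi(cl), "singleton")
  expect_equal(dplyr::n_distinct(map$identity_key), 2)
})
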