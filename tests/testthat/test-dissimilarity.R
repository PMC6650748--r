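test_that("feature distances follow |a-b| and Euclidean rules", {
  sc <- matrix(c(3, 7, 1), 3, 1,
               dimnames = list(c("A", "B", "C"), "temporal_centroid"))
  vec <- matrix(c(0, 3, 1, 0, 4, 1), 3, 2,
                dimnames = list(c("A", "B", "C"), NULL))
  ft <- toy_feature_table(sc, vectors = vec)
  D <- feature_distance_matrix(ft, "temporal_centroid")
  expect_equal(D$values["A", "B"], 4)
  expect_equal(diag(D$values), rep(0, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(D$values))
  Dv <- feature_distance_matrix(ft, "cochleagram_median")
  expect_equal(Dv$values["A", "B"], 5)  # (0,0) vs (3,4)
  expect_error(feature_distance_matrix(ft, "no_such_feature"), "unknown")
  ft$scalars$temporal_centroid[2] <- NA
  expect_error(feature_distance_matrix(ft, "temporal_centroid"), "B")
})

test_that("Euclidean feature distances satisfy the triangle inequality", {
  set.seed(11)
  for (rep in 1:5) {
    vm <- matrix(rnorm(6 * 4), 6, 4)
    ft <- toy_feature_table(matrix(rnorm(6), 6, 1,
                                   dimnames = list(NULL, "f0_median")),
                            vectors = vm)
    D <- feature_distance_matrix(ft, "cochleagram_iqr")$values
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
    }
  }
})

test_that("rating aggregation averages cells and symmetrizes", {
  items <- c("A", "B")
  tab <- data.frame(participant = 1:2,
                    item_first = c("A", "B"), item_second = c("B", "A"),
                    rating = c(5L, 7L))
  M <- aggregate_ratings(tab, items)
  expect_equal(M$values["A", "B"], 5)
  expect_equal(M$values["B", "A"], 7)
  Ms <- aggregate_ratings(tab, items, symmetrize = TRUE)
  expect_equal(Ms$values["A", "B"], 6)

  all9 <- data.frame(participant = 1,
                     item_first = c("A", "B"), item_second = c("B", "A"),
                     rating = c(9L, 9L))
  expect_true(all(aggregate_ratings(all9, items)$values[
    upper.tri(diag(2)) | lower.tri(diag(2))] == 9))

  # mean invariance: a table concatenated with itself aggregates the same
  expect_equal(aggregate_ratings(rbind(tab, tab), items)$values,
               M$values)
  # uncovered pairs are named
  expect_error(aggregate_ratings(tab[1, ], items), "uncovered")
})

test_that("noise-free rater tables aggregate to the generating matrix", {
  ft <- default_features()
  model <- rater_model(response_noise_sd = 0,
                       participant_criterion_sd = 0)
  tab <- simulate_ratings(ft, model, n_participants = 2, seed = 1)
  got <- aggregate_ratings(tab, ft$items, symmetrize = TRUE)$values
  # reconstruct the expected-rating matrix from the model definition
  w <- model$feature_weights
  n <- length(ft$items)
  comb <- matrix(0, n, n)
  ut <- upper.tri(comb)
  for (nm in names(w)) {
    D <- feature_distance_matrix(ft, nm)$values
    v <- D[ut]
    comb <- comb + w[[nm]] * (D - mean(v)) / sd(v)
  }
  z <- (comb - mean(comb[ut])) / sd(comb[ut])
  expected <- round(1 + 8 * plogis(model$slope * z))
  expect_equal(got[ut], expected[ut], ignore_attr = TRUE)
})

test_that("the pairing note rule picks the vowel note or E3", {
  set <- default_set()
  voc <- names(set$note_table)[1]
  expect_equal(pairing_note_rule(voc, "trombone", set),
               unname(set$note_table[voc]))
  expect_equal(pairing_note_rule("trombone", voc, set),
               unname(set$note_table[voc]))
  expect_equal(pairing_note_rule("trombone", "impact_1", set), "E3")
  expect_equal(pairing_note_rule("trombone", "guitar", set), "E3")
  expect_true(is.na(pairing_note_rule("m1_a", "m2_i", set)))
  expect_error(pairing_note_rule("nope", "trombone", set), "unknown")
})

test_that("category subsets have the expected pair counts", {
  ft <- default_features()
  D <- feature_distance_matrix(ft, "aperiodicity_median")
  expect_equal(nrow(subset_vector(D, "vocal", "vocal")), 66L)
  expect_equal(nrow(subset_vector(D, "environmental", "instrument")),
               144L)
  expect_equal(nrow(subset_vector(D, "all", "all")), 630L)
  expect_error(subset_vector(D, "plasma", "plasma"), "empty subset")
})
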