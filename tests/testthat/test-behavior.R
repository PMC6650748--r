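make_trials <- function(conf_counts, items, participant = 1L) {
  # expand a counts matrix into a trial table
  idx <- which(conf_counts > 0, arr.ind = TRUE)
  do.call(rbind, lapply(seq_len(nrow(idx)), function(k) {
    data.frame(participant = participant,
               stimulus = items[idx[k, 1]], response = items[idx[k, 2]],
               count = conf_counts[idx[k, 1], idx[k, 2]])
  })) -> df
  df[rep(seq_len(nrow(df)), df$count), c("participant", "stimulus",
                                         "response")]
}

test_that("item accuracy is the diagonal over presentations", {
  items <- c("a", "b", "c")
  M <- diag(c(10L, 10L, 10L)); dimnames(M) <- list(items, items)
  acc <- item_accuracy(make_trials(M, items), items)
  expect_true(all(acc == 1))

  M2 <- matrix(c(7, 3, 0, 0, 10, 0, 0, 0, 10), 3, byrow = TRUE,
               dimnames = list(items, items))
  acc2 <- item_accuracy(make_trials(M2, items), items)
  expect_equal(acc2[1, "a"], 0.7)
  expect_error(item_accuracy(make_trials(M2[1:2, , drop = FALSE], items),
                             items), "zero presentations")
})

test_that("subcategory recoding never lowers accuracy", {
  items <- c("a1", "a2", "b1")
  sub <- c(a1 = "A", a2 = "A", b1 = "B")
  M <- matrix(c(5, 5, 0,
                4, 6, 0,
                0, 0, 10), 3, byrow = TRUE,
              dimnames = list(items, items))
  tr <- make_trials(M, items)
  raw <- item_accuracy(tr, items)
  rec <- recode_subcategory(tr, items, sub)
  expect_true(all(rec >= raw))
  expect_true(all(rec[, c("a1", "a2")] == 1))  # all confusions within A
  expect_error(recode_subcategory(tr, items, sub[1:2]), "unmapped")

  # property on the simulated identifier: recoded >= raw everywhere
  ft <- default_features()
  trials <- simulate_identification(ft, n_participants = 5, seed = 4)
  raw_s <- item_accuracy(trials, ft$items)
  rec_s <- recode_subcategory(trials, ft$items,
                              setNames(ft$subcategories, ft$items))
  expect_true(all(rec_s >= raw_s))
})

test_that("accuracy-versus-chance tests behave at the extremes", {
  acc <- matrix(1, nrow = 10, ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
  res <- accuracy_vs_chance(acc, 1 / 36)
  expect_true(all(res$p == res$p[1]))
  expect_lt(res$p[1], 0.01)  # minimal attainable for n = 10

  # accuracies symmetric around chance: p near 0.5 on average over items
  set.seed(3)
  sym <- matrix(1 / 36 + rnorm(50 * 40, 0, 0.01), 50, 40,
                dimnames = list(NULL, paste0("i", 1:40)))
  res2 <- accuracy_vs_chance(sym, 1 / 36)
  expect_lt(abs(mean(res2$p) - 0.5), 0.1)

  expect_error(accuracy_vs_chance(acc[1, , drop = FALSE], 1 / 36),
               "2 participants")
})

test_that("confusion-dissimilarity correlation recovers planted relations", {
  items <- paste0("s", 1:8)
  set.seed(12)
  R <- matrix(runif(64, 1, 9), 8, 8, dimnames = list(items, items))
  R <- (R + t(R)) / 2; diag(R) <- NA
  ratings <- dissim_matrix(R, items, kind = "behavioral_rating",
                           value_range = c(1, 9))
  # confusions decrease with rated dissimilarity
  C <- round(100 * exp(-((R + t(R)) / 2) / 2)); diag(C) <- 100
  tau <- confusion_dissim_correlation(C, ratings)
  expect_lt(tau, -0.5)

  # a confusion matrix equal to the ratings correlates perfectly
  C2 <- R; diag(C2) <- 1
  expect_equal(confusion_dissim_correlation(C2, ratings), 1)

  # restricted mode drops diagonal and empty cells; diagonal-only fails
  C3 <- diag(8) * 10; dimnames(C3) <- list(items, items)
  expect_error(confusion_dissim_correlation(C3, ratings,
                                            mode = "restricted"),
               "no off-diagonal")

  # consistent reordering of both matrices leaves tau unchanged
  perm <- sample(8)
  ratings_p <- dissim_matrix(R[perm, perm], items[perm],
                             kind = "behavioral_rating",
                             value_range = c(1, 9))
  expect_equal(confusion_dissim_correlation(C[perm, perm], ratings_p),
               tau, tolerance = 1e-12)
})

test_that("split-half reliability and Spearman-Brown behave as defined", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)

  ft <- default_features()
  noiseless <- rater_model(response_noise_sd = 0,
                           participant_criterion_sd = 0)
  tab <- simulate_ratings(ft, noiseless, n_participants = 8, seed = 5)
  rel <- split_half_reliability(tab, n_splits = 5, seed = 1)
  expect_equal(rel$reliability, 1)

  noisy <- simulate_ratings(ft, n_participants = 12, seed = 6)
  rel2 <- split_half_reliability(noisy, n_splits = 10, seed = 2)
  expect_gt(rel2$reliability, 0.8)
  expect_lt(rel2$reliability, 1)

  expect_error(split_half_reliability(tab[tab$participant <= 3, ]),
               "4 participants")
})
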