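test_that("kendall_tau matches hand values and handles degenerate input", {
  expect_equal(kendall_tau(1:3, 1:3), 1)
  expect_equal(kendall_tau(1:3, 3:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  expect_warning(tau <- kendall_tau(c(1, 1, 1), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(tau))
  expect_error(kendall_tau(1:3, 1:4))
})

test_that("kendall_tau equals the brute-force pair-count oracle exactly", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(3:50, 1)
    x <- sample(seq_len(max(2, n %/% 2)), n, replace = TRUE)  # with ties
    y <- rnorm(n)
    if (rep %% 3 == 0) y <- sample(seq_len(5), n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), kendall_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("kendall_tau agrees with the base-R estimate on tied data", {
  set.seed(7)
  x <- sample(1:6, 40, replace = TRUE)
  y <- sample(1:6, 40, replace = TRUE)
  expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"),
               tolerance = 1e-12)
})

test_that("semi-partial tau reduces correctly and flags collinearity", {
  set.seed(21)
  y <- rnorm(60); x <- rnorm(60)
  expect_equal(semi_partial_tau(y, x, Z = NULL), kendall_tau(y, x))
  expect_warning(sp <- semi_partial_tau(y, x, Z = cbind(x, rnorm(60))),
                 "degenerate")
  expect_true(is.na(sp))
  # with x independent of Z, the residual barely changes x's ranks
  reps <- replicate(40, {
    y <- rnorm(80); x <- rnorm(80); Z <- matrix(rnorm(160), 80)
    semi_partial_tau(y, x, Z) - kendall_tau(y, x)
  })
  expect_lt(mean(abs(reps)), 0.05)
})

test_that("permutation p-values hit their bounds and formula", {
  y <- 1:20
  pt <- permutation_test(y, y + rnorm(20, sd = 1e-4), n = 99, seed = 5)
  expect_equal(pt$p, (pt$r + 1) / 100)
  expect_equal(pt$r, 0)            # observed exceeds every null
  expect_equal(pt$p, 1 / 100)

  anti <- permutation_test(y, rev(y), n = 99, seed = 5)
  expect_equal(anti$p, 1)          # observed below all null statistics

  # reproducibility of the exceedance count on fixed data
  set.seed(1)
  yy <- rnorm(30); xx <- rnorm(30)
  a <- permutation_test(yy, xx, n = 199, seed = 11)
  b <- permutation_test(yy, xx, n = 199, seed = 11)
  expect_identical(a$r, b$r)
  c <- permutation_test(yy, xx, n = 199, seed = 12)
  expect_false(identical(a$r, c$r) && identical(a$p, c$p))
})

test_that("permutation p-values are uniform under independence", {
  set.seed(31)
  ps <- replicate(400, {
    permutation_test(rnorm(25), rnorm(25), n = 199,
                     seed = sample.int(1e6, 1))$p
  })
  expect_gte(min(ps), 1 / 200)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("FDR correction matches the hand BH oracle", {
  expect_equal(fdr_correct(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_correct(0.37), 0.37)
  set.seed(8)
  p <- runif(25)
  expect_equal(fdr_correct(p), bh_oracle(p), tolerance = 1e-12)
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("rsa_report applies the F0 inclusion rule per subset", {
  ft <- default_features()
  D <- feature_distance_matrix(ft, "spectral_centroid_median")
  behavior <- dissim_matrix(1 + 8 * D$values / max(D$values), ft$items,
                            categories = ft$categories,
                            kind = "behavioral_rating",
                            value_range = c(1, 9))
  rep <- rsa_report(behavior, ft, n = 49, seed = 3)
  feats_of <- function(s) {
    sort(unique(rep$feature[rep$subset == s]))
  }
  expect_true(all(c("f0_median", "f0_iqr") %in% feats_of("voc_voc")))
  expect_true("f0_iqr" %in% feats_of("voc_inst"))
  expect_false("f0_median" %in% feats_of("voc_inst"))
  expect_false(any(c("f0_median", "f0_iqr") %in% feats_of("env_inst")))
  expect_false(any(c("f0_median", "f0_iqr") %in% feats_of("overall")))
  expect_equal(sort(unique(rep$subset)), sort(rsa_subsets()$subset))

  # behavior built from one feature's own distances: that feature is tau=1
  ov <- rep[rep$subset == "overall" & rep$statistic == "tau", ]
  expect_equal(ov$tau[ov$feature == "spectral_centroid_median"], 1)
  expect_identical(ov$feature[which.max(ov$tau)],
                   "spectral_centroid_median")
  # p lower bound and r range
  expect_true(all(rep$p >= 1 / (49 + 1), na.rm = TRUE))
  expect_true(all(rep$r <= rep$n, na.rm = TRUE))
})

test_that("rsa_report permutation counts reproduce under a fixed seed", {
  ft <- default_features()
  lists <- counterbalance_lists(ft$items)
  tab <- simulate_ratings(ft, n_participants = 6, lists = lists,
                          seed = 2)
  behavior <- aggregate_ratings(tab, ft$items)
  sub2 <- rsa_subsets()[rsa_subsets()$subset %in% c("voc_voc"), ]
  r1 <- rsa_report(behavior, ft, subsets = sub2, n = 99, seed = 17)
  r2 <- rsa_report(behavior, ft, subsets = sub2, n = 99, seed = 17)
  expect_identical(r1$r, r2$r)
  expect_identical(r1$tau, r2$tau)
})
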