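# Representational similarity analysis: standard and semi-partial Kendall
# tau between behavioral and acoustic item-pair dissimilarity vectors, with
# permutation-based one-sided inference and Benjamini-Hochberg FDR control.

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall tau computed by an O(n log n) merge-sort
#' algorithm.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The tau-b coefficient, or `NA` (with a warning) when either
#'   vector has zero variance.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed",
                                 call. = FALSE)
  tau <- kendall_tau_cpp(as.numeric(x), as.numeric(y))
  if (is.na(tau)) warning("kendall_tau undefined: zero variance input")
  tau
}

#' Semi-partial Kendall tau
#'
#' Correlation between `y` and the target predictor `x` after removing the
#' other predictors' shared variance from `x` only: `x` and the columns of
#' `Z` are rank-transformed, `rank(x)` is residualized on `rank(Z)` by
#' least squares, and `kendall_tau(y, residual)` is returned. With empty
#' `Z` this equals `kendall_tau(y, x)`.
#'
#' @param y Outcome vector (behavioral dissimilarities).
#' @param x Target predictor vector.
#' @param Z Matrix (or vector) of control predictors, or `NULL`.
#' @return The semi-partial tau, or `NA` (with a warning) when the
#'   residual is degenerate (e.g., `x` collinear with `Z`).
#' @export
semi_partial_tau <- function(y, x, Z = NULL) {
  r <- .semi_partial_residual(x, Z)
  if (is.null(r)) {
    warning("semi_partial_tau degenerate: residual has (near-)zero ",
            "variance")
    return(NA_real_)
  }
  kendall_tau(y, r)
}

# rank-residualize x on Z; NULL when degenerate
.semi_partial_residual <- function(x, Z = NULL) {
  rx <- rank(x)
  if (is.null(Z) || NCOL(Z) == 0L) {
    if (stats::sd(rx) == 0) return(NULL)
    return(rx)
  }
  Zr <- apply(as.matrix(Z), 2, rank)
  fit <- stats::lm.fit(cbind(1, Zr), rx)
  r <- stats::residuals(fit)
  if (stats::sd(r) < 1e-8 * max(1, stats::sd(rx))) return(NULL)
  r
}

#' One-sided permutation test for a rank correlation
#'
#' The correspondence between outcome and predictor is broken by permuting
#' `y` over `n` iterations; `r` counts null statistics that met or
#' exceeded the observed statistic, and `p = (r + 1) / (n + 1)`. For the
#' semi-partial statistic the target predictor is residualized on `Z` once
#' (the residual is fixed under permutation of `y`).
#'
#' @param y Outcome vector.
#' @param x Target predictor vector.
#' @param Z Control predictors for `statistic = "semi_partial"`, or
#'   `NULL`.
#' @param statistic `"tau"` or `"semi_partial"`.
#' @param n Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return A list with `observed`, `r` (exceedance count), `n`, and `p`.
#' @export
permutation_test <- function(y, x, Z = NULL,
                             statistic = c("tau", "semi_partial"),
                             n = 10000, seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(n >= 1)
  v <- if (statistic == "tau") as.numeric(x) else {
    r <- .semi_partial_residual(x, Z)
    if (is.null(r)) {
      return(list(observed = NA_real_, r = NA_real_, n = n, p = NA_real_))
    }
    as.numeric(r)
  }
  obs <- kendall_tau_cpp(as.numeric(y), v)
  if (is.na(obs)) {
    return(list(observed = NA_real_, r = NA_real_, n = n, p = NA_real_))
  }
  r_count <- kendall_perm_count_cpp(as.numeric(y), v, as.integer(n), obs,
                                    as.integer(seed) %% .Machine$integer.max)
  list(observed = obs, r = r_count, n = n, p = (r_count + 1) / (n + 1))
}

#' Benjamini-Hochberg FDR correction
#'
#' @param p Vector of p-values in [0, 1] (`NA` allowed and preserved).
#' @return Step-up adjusted p-values.
#' @export
fdr_correct <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' The seven analysis subsets
#'
#' Overall plus the three within-category and three between-category
#' subsets, with the F0-feature inclusion rule for each: F0 median and IQR
#' enter the vocal-vocal analysis, F0 IQR the vocal-instrument analysis,
#' and neither anywhere else.
#'
#' @return A data frame with `subset`, `category_a`, `category_b`,
#'   `include_f0`.
#' @export
rsa_subsets <- function() {
  data.frame(
    subset = c("overall", "env_env", "inst_inst", "voc_voc", "env_inst",
               "env_voc", "voc_inst"),
    category_a = c("all", "environmental", "instrument", "vocal",
                   "environmental", "environmental", "vocal"),
    category_b = c("all", "environmental", "instrument", "vocal",
                   "instrument", "vocal", "instrument"),
    include_f0 = c("none", "none", "none", "both", "none", "none", "iqr"),
    stringsAsFactors = FALSE)
}

#' Full RSA report
#'
#' For each subset of item pairs (overall and the six within/between
#' category subsets), computes the standard and semi-partial Kendall tau
#' of the behavioral dissimilarity vector against each applicable acoustic
#' feature distance vector, with one-sided permutation p-values and
#' Benjamini-Hochberg correction within each subset-by-statistic family.
#' Each (subset, feature, statistic) cell uses its own permutation stream
#' seeded from the master seed.
#'
#' @param behavior A behavioral `dissim_matrix` (symmetrized internally
#'   for the default unordered-pair mode).
#' @param features A [feature_table()] covering the same items.
#' @param subsets Subset definition table as from [rsa_subsets()].
#' @param n Permutations per test (default 10000).
#' @param seed Master integer seed.
#' @param pair_mode `"unordered"` (630 pairs for 36 items; default) or
#'   `"ordered"` (1260; the behavioral matrix is used asymmetrically and
#'   each acoustic predictor value appears twice).
#' @return A data frame of class `rsa_report` with columns `subset`,
#'   `feature`, `statistic`, `tau`, `r`, `n`, `p`, `p_fdr`.
#' @export
rsa_report <- function(behavior, features, subsets = rsa_subsets(),
                       n = 10000, seed = 1,
                       pair_mode = c("unordered", "ordered")) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(inherits(behavior, "dissim_matrix"),
            inherits(features, "feature_table"))
  if (!identical(behavior$items, features$items)) {
    stop("behavior and features must cover the same items in the same ",
         "order", call. = FALSE)
  }
  cats <- features$categories
  B <- behavior$values
  Bsym <- (B + t(B)) / 2
  if (any(is.na(Bsym[upper.tri(Bsym)]))) {
    stop("behavioral matrix has missing off-diagonal cells",
         call. = FALSE)
  }

  # enumerate tests in a fixed order, then draw one sub-seed per test
  all_feats <- unique(unlist(lapply(subsets$include_f0,
                                    rsa_feature_names)))
  dist_mats <- lapply(all_feats, function(nm) {
    feature_distance_matrix(features, nm)$values
  })
  names(dist_mats) <- all_feats

  rows <- list()
  for (s in seq_len(nrow(subsets))) {
    feats <- rsa_feature_names(subsets$include_f0[s])
    idx <- subset_pairs(cats, subsets$category_a[s],
                        subsets$category_b[s])
    if (pair_mode == "ordered") {
      idx <- rbind(idx, idx[, c(2, 1)])
      y <- B[idx]
    } else {
      y <- Bsym[idx]
    }
    X <- vapply(feats, function(nm) dist_mats[[nm]][idx],
                numeric(nrow(idx)))
    for (f in seq_along(feats)) {
      rows[[length(rows) + 1L]] <- list(
        subset = subsets$subset[s], feature = feats[f],
        y = y, x = X[, f], Z = X[, -f, drop = FALSE])
    }
  }

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          2L * length(rows))
  out <- vector("list", 2L * length(rows))
  for (k in seq_along(rows)) {
    rw <- rows[[k]]
    for (st in c("tau", "semi_partial")) {
      slot <- 2L * (k - 1L) + if (st == "tau") 1L else 2L
      pt <- permutation_test(rw$y, rw$x,
                             Z = if (st == "tau") NULL else rw$Z,
                             statistic = st, n = n,
                             seed = sub_seeds[slot])
      out[[slot]] <- data.frame(
        subset = rw$subset, feature = rw$feature, statistic = st,
        tau = pt$observed, r = pt$r, n = pt$n, p = pt$p,
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- do.call(rbind, out)
  rep_df$p_fdr <- NA_real_
  for (s in unique(rep_df$subset)) {
    for (st in c("tau", "semi_partial")) {
      sel <- rep_df$subset == s & rep_df$statistic == st
      rep_df$p_fdr[sel] <- fdr_correct(rep_df$p[sel])
    }
  }
  class(rep_df) <- c("rsa_report", "data.frame")
  rep_df
}
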