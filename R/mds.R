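# Ordinal (nonmetric) multidimensional scaling by stress majorization
# (SMACOF) with primary-tie monotone regression, plus the scree utility
# and dimension-feature correlations.

# pooled adjacent violators: least-squares non-decreasing fit, unit weights
.pava <- function(y) {
  n <- length(y)
  if (n < 2L) return(y)
  vals <- y
  wts <- rep(1, n)
  idx <- 1L
  start <- integer(n)
  start[1L] <- 1L
  for (i in 2:n) {
    idx <- idx + 1L
    vals[idx] <- y[i]
    wts[idx] <- 1
    start[idx] <- i
    while (idx > 1L && vals[idx - 1L] > vals[idx]) {
      v <- (vals[idx - 1L] * wts[idx - 1L] + vals[idx] * wts[idx]) /
        (wts[idx - 1L] + wts[idx])
      wts[idx - 1L] <- wts[idx - 1L] + wts[idx]
      vals[idx - 1L] <- v
      idx <- idx - 1L
    }
  }
  out <- numeric(n)
  ends <- if (idx == 1L) n else c(start[2:idx] - 1L, n)
  for (b in seq_len(idx)) {
    out[start[b]:ends[b]] <- vals[b]
  }
  out
}

# monotone (isotonic) fit of d against the rank order of delta, primary
# approach to ties: within a tie block of delta, pairs are ordered by d so
# they may untie freely
.monotone_fit <- function(delta, d) {
  ord <- order(delta, d)
  dhat <- numeric(length(d))
  dhat[ord] <- .pava(d[ord])
  dhat
}

.smacof_engine <- function(delta_vec, X, pair_idx, tol, max_iter) {
  n <- nrow(X)
  m <- length(delta_vec)
  X <- scale(X, scale = FALSE)
  stress_seq <- numeric(0)
  prev_raw <- Inf
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((X[pair_idx[, 1], , drop = FALSE] -
                         X[pair_idx[, 2], , drop = FALSE])^2))
    dhat <- .monotone_fit(delta_vec, d)
    dhat <- dhat * sqrt(m / sum(dhat^2))
    raw <- sqrt(sum((dhat - d)^2) / m)
    stress_seq <- c(stress_seq, raw)
    if (is.finite(prev_raw) && prev_raw - raw < tol * max(prev_raw, 1e-12)) {
      break
    }
    prev_raw <- raw
    # Guttman transform with unit weights
    ratio <- ifelse(d > 1e-12, dhat / d, 0)
    B <- matrix(0, n, n)
    B[pair_idx] <- -ratio
    B[pair_idx[, c(2, 1), drop = FALSE]] <- -ratio
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    X <- scale(X, scale = FALSE)
  }
  d <- sqrt(rowSums((X[pair_idx[, 1], , drop = FALSE] -
                       X[pair_idx[, 2], , drop = FALSE])^2))
  dhat <- .monotone_fit(delta_vec, d)
  dhat <- dhat * sqrt(m / sum(dhat^2))
  stress1 <- if (sum(d^2) > 0) sqrt(sum((dhat - d)^2) / sum(d^2)) else 0
  list(X = X, stress = stress1, stress_sequence = stress_seq)
}

#' Ordinal MDS by stress majorization
#'
#' Fits a nonmetric (ordinal) MDS configuration to a symmetrized
#' dissimilarity matrix via SMACOF: alternating monotone regression of the
#' configuration distances on the dissimilarity ranks (primary tie
#' handling) and Guttman-transform updates. The best of `n_starts`
#' configurations (classical-scaling start plus random starts) is kept and
#' rotated to principal axes; axis signs put each dimension's largest
#' absolute coordinate positive. For behavioral rating matrices the
#' diagonal is set to the scale minimum before fitting (identical pairs
#' were not presented).
#'
#' @param matrix A `dissim_matrix` (or plain square matrix).
#' @param n_dimensions Embedding dimensionality (default 3).
#' @param n_starts Number of starts (default 8; the first is classical
#'   scaling).
#' @param tol Relative majorized-stress change convergence tolerance
#'   (default 1e-6).
#' @param max_iter Maximum majorization iterations per start (default
#'   1000).
#' @param seed Integer seed for the random starts.
#' @return An object of class `mds_solution` with `coordinates` (items x
#'   dimensions), `stress` (Kruskal stress-1), `n_dimensions`,
#'   `stress_sequence` (majorized stress per iteration of the best start,
#'   non-increasing), `n_starts`.
#' @export
ordinal_mds <- function(matrix, n_dimensions = 3, n_starts = 8,
                        tol = 1e-6, max_iter = 1000, seed = 1) {
  if (inherits(matrix, "dissim_matrix")) {
    vals <- matrix$values
    items <- matrix$items
    vr <- matrix$value_range
  } else {
    vals <- as.matrix(matrix)
    items <- rownames(vals) %||% paste0("item", seq_len(nrow(vals)))
    vr <- NULL
  }
  if (nrow(vals) != ncol(vals)) stop("input must be square", call. = FALSE)
  n <- nrow(vals)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- if (!is.null(vr)) vr[1] else 0
  if (n <= n_dimensions) {
    stop("need more items than dimensions", call. = FALSE)
  }
  pair_idx <- which(upper.tri(vals), arr.ind = TRUE)
  delta_vec <- vals[pair_idx]

  # classical (Torgerson) start
  starts <- list(suppressWarnings(
    stats::cmdscale(stats::as.dist(vals), k = n_dimensions)))
  if (ncol(starts[[1]]) < n_dimensions) {
    pad <- matrix(0, n, n_dimensions - ncol(starts[[1]]))
    starts[[1]] <- cbind(starts[[1]], pad)
  }
  set.seed(seed)
  spread <- stats::sd(delta_vec)
  if (!is.finite(spread) || spread == 0) spread <- max(delta_vec, 1)
  for (s in seq_len(max(0L, n_starts - 1L))) {
    starts[[s + 1L]] <- matrix(stats::rnorm(n * n_dimensions), n,
                               n_dimensions) * spread
  }
  fits <- lapply(starts, function(X0) {
    .smacof_engine(delta_vec, X0, pair_idx, tol, max_iter)
  })
  best <- fits[[which.min(vapply(fits, `[[`, 0, "stress"))]]

  X <- scale(best$X, scale = FALSE)
  if (n_dimensions > 1L) {
    X <- X %*% svd(X)$v
  }
  for (k in seq_len(ncol(X))) {
    if (X[which.max(abs(X[, k])), k] < 0) X[, k] <- -X[, k]
  }
  dimnames(X) <- list(items, paste0("dim", seq_len(n_dimensions)))
  structure(
    list(coordinates = X, stress = best$stress,
         n_dimensions = n_dimensions,
         stress_sequence = best$stress_sequence, n_starts = n_starts),
    class = "mds_solution")
}

#' @export
print.mds_solution <- function(x, ...) {
  cat(sprintf("<mds_solution> %d items in %d dimensions, stress-1 %.4f\n",
              nrow(x$coordinates), x$n_dimensions, x$stress))
  invisible(x)
}

#' Stress by dimensionality
#'
#' Runs [ordinal_mds()] at each dimensionality from 1 to `max_dimensions`
#' with a shared seed.
#'
#' @inheritParams ordinal_mds
#' @param max_dimensions Highest dimensionality (< item count).
#' @return A data frame with `dimensions` and `stress`.
#' @export
stress_scree <- function(matrix, max_dimensions = 6, n_starts = 8,
                         tol = 1e-6, max_iter = 1000, seed = 1) {
  nitems <- if (inherits(matrix, "dissim_matrix")) {
    nrow(matrix$values)
  } else nrow(matrix)
  stopifnot(max_dimensions < nitems)
  stress <- vapply(seq_len(max_dimensions), function(k) {
    ordinal_mds(matrix, n_dimensions = k, n_starts = n_starts, tol = tol,
                max_iter = max_iter, seed = seed)$stress
  }, 0)
  data.frame(dimensions = seq_len(max_dimensions), stress = stress)
}

#' Correlate MDS dimensions with scalar acoustic features
#'
#' Kendall tau between item coordinates on each dimension and each scalar
#' feature value, with FDR correction within dimension. Axis reflection is
#' resolved by forcing a positive tau for the feature with the largest
#' absolute tau on each dimension.
#'
#' @param solution An [ordinal_mds()] result.
#' @param features A [feature_table()] covering the embedded items.
#' @param feature_names Scalar features to use (default
#'   [scalar_feature_names()]).
#' @return A list with `table` (data frame: `dimension`, `feature`, `tau`,
#'   `p`, `p_fdr`) and `solution` (the possibly reflected solution).
#' @export
dimension_feature_correlations <- function(solution, features,
                                           feature_names =
                                             scalar_feature_names()) {
  stopifnot(inherits(solution, "mds_solution"),
            inherits(features, "feature_table"))
  X <- solution$coordinates
  if (!all(rownames(X) %in% features$items)) {
    stop("features must cover the embedded items", call. = FALSE)
  }
  sc <- features$scalars[match(rownames(X), features$items), ]
  rows <- list()
  for (k in seq_len(ncol(X))) {
    taus <- vapply(feature_names, function(nm) {
      v <- sc[[nm]]
      if (stats::sd(v) == 0) return(NA_real_)
      suppressWarnings(kendall_tau(X[, k], v))
    }, 0)
    top <- which.max(abs(taus))
    if (length(top) == 1L && !is.na(taus[top]) && taus[top] < 0) {
      X[, k] <- -X[, k]
      taus <- -taus
    }
    ps <- vapply(seq_along(feature_names), function(fi) {
      v <- sc[[feature_names[fi]]]
      if (is.na(taus[fi])) return(NA_real_)
      suppressWarnings(stats::cor.test(X[, k], v, method = "kendall",
                                       exact = FALSE)$p.value)
    }, 0)
    rows[[k]] <- data.frame(
      dimension = k, feature = feature_names, tau = taus, p = ps,
      p_fdr = fdr_correct(ps), row.names = NULL,
      stringsAsFactors = FALSE)
  }
  solution$coordinates <- X
  list(table = do.call(rbind, rows), solution = solution)
}
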