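# Simulated behavioral responders with known ground truth: dissimilarity
# raters whose 1-9 responses are a noisy monotone function of weighted
# acoustic distances, and identifiers whose confusions concentrate among
# acoustically close items.

#' Rater model
#'
#' Expected ratings are a logistic squash of the z-scored weighted sum of
#' standardized feature distances onto the 1--9 scale; observed ratings add
#' a per-participant criterion shift and per-trial noise, then round and
#' clip to 1..9.
#'
#' @param feature_weights Named non-negative weights over
#'   [rsa_feature_names()] entries (at least one positive). The default
#'   emphasizes aperiodicity, spectral variability, and the
#'   spectral/temporal envelope summaries.
#' @param response_noise_sd Trial noise SD in rating units (default 2,
#'   which puts the simulated split-half reliability near the ~0.98 level
#'   human raters reach on this design).
#' @param participant_criterion_sd Per-participant criterion shift SD in
#'   rating units (default 0.5).
#' @param slope Slope of the logistic monotone transform (default 1.2).
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(feature_weights = NULL, response_noise_sd = 2,
                        participant_criterion_sd = 0.5, slope = 1.2) {
  if (is.null(feature_weights)) {
    # spectral-envelope variability (cochleagram IQR) leads, with
    # aperiodicity and spectral variability next; the collinearity among
    # these features means the top weight must clearly dominate for the
    # generating feature to be identifiable from the ratings
    feature_weights <- c(
      cochleagram_iqr = 2.0,
      aperiodicity_median = 0.45,
      spectral_variability_median = 0.35,
      cochleagram_median = 0.35,
      spectral_centroid_median = 0.3,
      mps = 0.25,
      temporal_centroid = 0.2,
      spectral_centroid_iqr = 0.2,
      log_attack_time = 0.15,
      spectral_flatness_median = 0.1,
      spectral_flatness_iqr = 0.1)
  }
  if (any(feature_weights < 0) || !any(feature_weights > 0)) {
    stop("feature_weights must be non-negative with at least one ",
         "positive entry", call. = FALSE)
  }
  stopifnot(response_noise_sd >= 0, participant_criterion_sd >= 0,
            slope > 0)
  structure(list(feature_weights = feature_weights,
                 response_noise_sd = response_noise_sd,
                 participant_criterion_sd = participant_criterion_sd,
                 slope = slope),
            class = "rater_model")
}

#' Identifier model
#'
#' Response probabilities for stimulus i are proportional to
#' `exp(-d(i, j) / temperature + self_bias * [i == j])` over candidate
#' responses j, where d is the weighted standardized acoustic distance.
#'
#' @param temperature Softness of confusion (> 0; small values give
#'   near-perfect identification, large values approach uniform guessing).
#' @param self_bias Additive log-preference for the correct response
#'   (default 2).
#' @param feature_weights As in [rater_model()]; defaults shared.
#' @return A list of class `identifier_model`.
#' @export
identifier_model <- function(temperature = 0.5, self_bias = 2,
                             feature_weights = NULL) {
  stopifnot(temperature > 0)
  structure(list(temperature = temperature, self_bias = self_bias,
                 feature_weights = feature_weights %||%
                   rater_model()$feature_weights),
            class = "identifier_model")
}

# z-scored weighted combination of feature distance matrices; returns the
# full item x item matrix of combined distances (z-scoring over unordered
# pairs) plus the per-feature standardized matrices
.weighted_distances <- function(features, weights) {
  n <- length(features$items)
  ut <- upper.tri(matrix(0, n, n))
  comb <- matrix(0, n, n)
  for (nm in names(weights)) {
    if (weights[[nm]] == 0) next
    D <- feature_distance_matrix(features, nm)$values
    v <- D[ut]
    s <- stats::sd(v)
    if (s == 0) next
    comb <- comb + weights[[nm]] * (D - mean(v)) / s
  }
  comb[!ut & !t(ut)] <- 0   # zero diagonal
  (comb + t(comb)) / 2      # symmetric by construction; keep exact
}

#' Two complementary counterbalanced trial lists
#'
#' Every unordered item pair appears exactly once per list; the two lists
#' present the pair in opposite orders and jointly cover all ordered
#' pairs. Order within a list alternates deterministically by pair parity.
#'
#' @param items Item labels (>= 2 for non-empty lists).
#' @return A list of two data frames with columns `item_first`,
#'   `item_second`.
#' @export
counterbalance_lists <- function(items) {
  n <- length(items)
  if (n < 2L) {
    empty <- data.frame(item_first = character(0),
                        item_second = character(0),
                        stringsAsFactors = FALSE)
    return(list(empty, empty))
  }
  cmb <- t(utils::combn(seq_len(n), 2L))
  flip <- (cmb[, 1] + cmb[, 2]) %% 2L == 0L
  first1 <- ifelse(flip, cmb[, 2], cmb[, 1])
  second1 <- ifelse(flip, cmb[, 1], cmb[, 2])
  list(
    data.frame(item_first = items[first1], item_second = items[second1],
               stringsAsFactors = FALSE),
    data.frame(item_first = items[second1], item_second = items[first1],
               stringsAsFactors = FALSE))
}

#' Simulate trial-level dissimilarity ratings
#'
#' Each participant is assigned one of the two counterbalanced lists
#' (alternating) and rates their pairs in a random order split into three
#' equal blocks. Reproducible given the seed.
#'
#' @param features A [feature_table()].
#' @param model A [rater_model()].
#' @param n_participants Number of simulated raters.
#' @param lists Two complementary lists from [counterbalance_lists()].
#' @param seed Integer seed.
#' @return A rating table: data frame with `participant`, `item_first`,
#'   `item_second`, `rating` (integer 1--9), `block`.
#' @export
simulate_ratings <- function(features, model = rater_model(),
                             n_participants = 50,
                             lists = counterbalance_lists(features$items),
                             seed = 1) {
  stopifnot(inherits(features, "feature_table"),
            inherits(model, "rater_model"))
  if (n_participants == 0L) {
    return(data.frame(participant = integer(0),
                      item_first = character(0),
                      item_second = character(0), rating = integer(0),
                      block = integer(0), stringsAsFactors = FALSE))
  }
  comb <- .weighted_distances(features, model$feature_weights)
  n <- length(features$items)
  ut <- upper.tri(comb)
  z <- (comb - mean(comb[ut])) / stats::sd(comb[ut])
  expected <- 1 + 8 * stats::plogis(model$slope * z)
  dimnames(expected) <- list(features$items, features$items)

  set.seed(seed)
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    lst <- lists[[(p - 1L) %% 2L + 1L]]
    ord <- sample.int(nrow(lst))
    lst <- lst[ord, , drop = FALSE]
    crit <- stats::rnorm(1, 0, model$participant_criterion_sd)
    mu <- expected[cbind(lst$item_first, lst$item_second)]
    r <- mu + crit + stats::rnorm(nrow(lst), 0, model$response_noise_sd)
    n_block <- max(1L, ceiling(nrow(lst) / 3L))
    out[[p]] <- data.frame(
      participant = p,
      item_first = lst$item_first, item_second = lst$item_second,
      rating = as.integer(pmax(1, pmin(9, round(r)))),
      block = ((seq_len(nrow(lst)) - 1L) %/% n_block) + 1L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate identification responses
#'
#' Each participant identifies every item once per block; the instrument
#' note for each block is sampled at random from the pairing notes and
#' recorded in the output (response probabilities are computed from the
#' supplied feature table).
#'
#' @param features A [feature_table()].
#' @param model An [identifier_model()].
#' @param n_participants Number of simulated identifiers.
#' @param n_blocks Blocks per participant (default 10).
#' @param seed Integer seed.
#' @param notes Candidate block notes (default E3 plus the vowel-derived
#'   notes when available via attributes, else E3 only).
#' @return A trial table: data frame with `participant`, `block`,
#'   `block_note`, `stimulus`, `response`.
#' @export
simulate_identification <- function(features, model = identifier_model(),
                                    n_participants = 20, n_blocks = 10,
                                    seed = 1, notes = "E3") {
  stopifnot(inherits(features, "feature_table"),
            inherits(model, "identifier_model"))
  D <- .weighted_distances(features, model$feature_weights)
  ut <- upper.tri(D)
  D <- (D - min(D[ut])) / max(1e-12, diff(range(D[ut])))  # scale to [0,1]
  diag(D) <- 0
  score <- -D / model$temperature
  diag(score) <- diag(score) + model$self_bias
  P <- exp(score - apply(score, 1, max))
  P <- P / rowSums(P)
  items <- features$items
  set.seed(seed)
  out <- vector("list", n_participants * n_blocks)
  k <- 0L
  for (p in seq_len(n_participants)) {
    for (b in seq_len(n_blocks)) {
      k <- k + 1L
      note <- notes[sample.int(length(notes), 1L)]
      ord <- sample.int(length(items))
      resp <- vapply(ord, function(i) {
        items[sample.int(length(items), 1L, prob = P[i, ])]
      }, "")
      out[[k]] <- data.frame(
        participant = p, block = b, block_note = note,
        stimulus = items[ord], response = resp,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
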