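# Identification-side analyses and rating reliability: item accuracy,
# chance comparisons, subcategory recoding, confusion-dissimilarity
# correlation, and split-half reliability with the Spearman-Brown
# adjustment.

#' Pool identification trials into confusion counts
#'
#' @param trials Trial table from [simulate_identification()] (or any data
#'   frame with `participant`, `stimulus`, `response`).
#' @param items Item labels fixing the matrix order.
#' @param by_participant If `TRUE`, return a list of per-participant
#'   stimulus x response count matrices; otherwise a pooled matrix.
#' @return A counts matrix (stimulus rows, response columns), or a list of
#'   them.
#' @export
confusion_counts <- function(trials, items, by_participant = FALSE) {
  tab_one <- function(tr) {
    M <- table(factor(tr$stimulus, levels = items),
               factor(tr$response, levels = items))
    matrix(as.integer(M), nrow = length(items),
           dimnames = list(items, items))
  }
  if (!by_participant) return(tab_one(trials))
  lapply(split(trials, trials$participant), tab_one)
}

#' Per-participant, per-item identification accuracy
#'
#' @param trials Identification trial table with `participant`,
#'   `stimulus`, `response`.
#' @param items Item labels.
#' @return A participant x item matrix of proportions correct.
#' @export
item_accuracy <- function(trials, items) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  per <- confusion_counts(trials, items, by_participant = TRUE)
  acc <- t(vapply(per, function(M) {
    pres <- rowSums(M)
    if (any(pres == 0)) {
      stop("zero presentations for item(s): ",
           paste(items[pres == 0], collapse = ", "), call. = FALSE)
    }
    diag(M) / pres
  }, numeric(length(items))))
  rownames(acc) <- names(per)
  acc
}

#' Subcategory-recoded identification accuracy
#'
#' Any response falling within the stimulus's subcategory (instrument
#' family, vowel, or excitation medium) counts as correct.
#'
#' @inheritParams item_accuracy
#' @param subcategory_map Named character vector: item -> subcategory
#'   (total on `items`).
#' @return A participant x item matrix of recoded proportions correct.
#' @export
recode_subcategory <- function(trials, items, subcategory_map) {
  if (any(!items %in% names(subcategory_map))) {
    stop("unmapped item(s): ",
         paste(setdiff(items, names(subcategory_map)), collapse = ", "),
         call. = FALSE)
  }
  sub <- subcategory_map[items]
  same_sub <- outer(sub, sub, "==")
  per <- confusion_counts(trials, items, by_participant = TRUE)
  acc <- t(vapply(per, function(M) {
    pres <- rowSums(M)
    if (any(pres == 0)) {
      stop("zero presentations for item(s): ",
           paste(items[pres == 0], collapse = ", "), call. = FALSE)
    }
    rowSums(M * same_sub) / pres
  }, numeric(length(items))))
  rownames(acc) <- names(per)
  acc
}

#' One-tailed tests of item accuracy against chance
#'
#' Wilcoxon signed-rank tests (alternative: greater) of the per-participant
#' accuracies for each item against `chance_level`, with Benjamini-Hochberg
#' correction across items.
#'
#' @param accuracy Participant x item accuracy matrix (from
#'   [item_accuracy()] or [recode_subcategory()]; >= 2 participants).
#' @param chance_level Chance proportion (e.g., `1/36` across all items,
#'   `1/12` within category).
#' @return A data frame with `item`, `mean_accuracy`, `p`, `p_fdr`.
#' @export
accuracy_vs_chance <- function(accuracy, chance_level) {
  if (nrow(accuracy) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  p <- vapply(seq_len(ncol(accuracy)), function(j) {
    v <- accuracy[, j]
    if (all(v == chance_level)) return(NA_real_)  # degenerate: all at chance
    suppressWarnings(
      stats::wilcox.test(v, mu = chance_level,
                         alternative = "greater")$p.value)
  }, 0)
  data.frame(item = colnames(accuracy),
             mean_accuracy = colMeans(accuracy),
             p = p, p_fdr = fdr_correct(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Correlate confusion rates with dissimilarity ratings
#'
#' Both matrices are symmetrized by averaging entries across their
#' diagonals. In `mode = "full"` the diagonal is included, with the rating
#' diagonal set to the scale minimum (1); in `mode = "restricted"` the
#' diagonal and zero-confusion cells are dropped. More confusable pairs
#' are expected to receive lower dissimilarity ratings, so the correlation
#' is negative.
#'
#' @param confusion Pooled stimulus x response counts matrix.
#' @param ratings A behavioral `dissim_matrix`.
#' @param mode `"full"` or `"restricted"`.
#' @return The Kendall tau between confusion and rating values.
#' @export
confusion_dissim_correlation <- function(confusion, ratings,
                                         mode = c("full", "restricted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ratings, "dissim_matrix"))
  R <- ratings$values
  if (!identical(rownames(confusion), ratings$items)) {
    stop("confusion and ratings must cover the same items",
         call. = FALSE)
  }
  C <- (confusion + t(confusion)) / 2
  diag(R) <- if (!is.null(ratings$value_range)) ratings$value_range[1] else 1
  R <- (R + t(R)) / 2
  if (mode == "full") {
    keep <- upper.tri(C, diag = TRUE)
  } else {
    keep <- upper.tri(C) & C > 0
    if (!any(keep)) {
      stop("restricted mode: no off-diagonal confusions", call. = FALSE)
    }
  }
  kendall_tau(C[keep], R[keep])
}

#' Split-half reliability of dissimilarity ratings
#'
#' Participants are split into random halves; per-half mean ratings per
#' unordered item pair are correlated (Pearson, over pairs observed in
#' both halves; unordered pairs keep both halves covered under the
#' counterbalanced two-list design) and adjusted by the Spearman-Brown
#' prophecy formula `2r / (1 + r)`; the mean over `n_splits` random
#' splits is returned.
#'
#' @param table Rating table (>= 4 participants).
#' @param n_splits Number of random splits (default 100).
#' @param seed Integer seed.
#' @return A list with `reliability` (mean adjusted value), `splits`
#'   (per-split adjusted values).
#' @export
split_half_reliability <- function(table, n_splits = 100, seed = 1) {
  ids <- unique(table$participant)
  if (length(ids) < 4L) stop("need at least 4 participants",
                             call. = FALSE)
  key <- paste(pmin(table$item_first, table$item_second),
               pmax(table$item_first, table$item_second), sep = "\r")
  set.seed(seed)
  vals <- vapply(seq_len(n_splits), function(s) {
    half <- sample(ids, floor(length(ids) / 2))
    in_a <- table$participant %in% half
    ma <- tapply(table$rating[in_a], key[in_a], mean)
    mb <- tapply(table$rating[!in_a], key[!in_a], mean)
    common <- intersect(names(ma), names(mb))
    r <- stats::cor(ma[common], mb[common])
    spearman_brown(r)
  }, 0)
  list(reliability = mean(vals), splits = vals)
}

#' Spearman-Brown prophecy adjustment
#'
#' @param r Split-half correlation.
#' @return `2 * r / (1 + r)`.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)
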