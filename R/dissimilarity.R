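# Pairwise dissimilarity structures: acoustic feature distance matrices,
# behavioral rating aggregation, the vocal-instrument note pairing rule,
# and within/between-category subsetting.

#' Construct a dissimilarity matrix object
#'
#' @param values Square numeric matrix.
#' @param items Item labels (row/column order).
#' @param categories Per-item category labels.
#' @param kind `"behavioral_rating"`, `"acoustic_distance"`, or
#'   `"confusion"`.
#' @param value_range Two-element range for rating scales (e.g., `c(1, 9)`),
#'   or `NULL`.
#' @return An object of class `dissim_matrix`.
#' @export
dissim_matrix <- function(values, items, categories = NULL,
                          kind = c("acoustic_distance",
                                   "behavioral_rating", "confusion"),
                          value_range = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("dissimilarity matrix must be square", call. = FALSE)
  }
  stopifnot(length(items) == nrow(values))
  dimnames(values) <- list(items, items)
  structure(list(values = values, items = items, categories = categories,
                 kind = kind, value_range = value_range),
            class = "dissim_matrix")
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("<dissim_matrix> %d x %d (%s)\n", nrow(x$values),
              ncol(x$values), x$kind))
  invisible(x)
}

#' Item-pair distance matrix for one acoustic feature
#'
#' Scalar features use the absolute difference between the two items'
#' values; vector-valued representations (`cochleagram_median`,
#' `cochleagram_iqr`, `mps`) use the Euclidean distance.
#'
#' @param features A [feature_table()].
#' @param feature_name One of [rsa_feature_names()] /
#'   [scalar_feature_names()].
#' @return A symmetric, zero-diagonal `dissim_matrix` of kind
#'   `"acoustic_distance"`.
#' @export
feature_distance_matrix <- function(features, feature_name) {
  stopifnot(inherits(features, "feature_table"))
  if (feature_name %in% c("cochleagram_median", "cochleagram_iqr",
                          "mps")) {
    M <- features[[feature_name]]
    bad <- rowSums(!is.finite(M)) > 0
    if (any(bad)) {
      stop("missing feature values for item(s): ",
           paste(features$items[bad], collapse = ", "), call. = FALSE)
    }
    D <- as.matrix(stats::dist(M))
  } else {
    v <- features$scalars[[feature_name]]
    if (is.null(v)) stop("unknown feature: ", feature_name, call. = FALSE)
    if (any(!is.finite(v))) {
      stop("missing feature values for item(s): ",
           paste(features$items[!is.finite(v)], collapse = ", "),
           call. = FALSE)
    }
    D <- abs(outer(v, v, "-"))
  }
  dissim_matrix(D, features$items, features$categories,
                kind = "acoustic_distance")
}

#' Aggregate trial-level ratings into a group dissimilarity matrix
#'
#' Cell (i, j) is the mean rating over all trials with first item i and
#' second item j. Every ordered pair must be covered by at least one
#' rating (the union of two counterbalanced lists guarantees this).
#'
#' @param table A rating table: data frame with columns `participant`,
#'   `item_first`, `item_second`, `rating`.
#' @param items Item labels fixing the matrix order.
#' @param symmetrize Average cell (i, j) with (j, i) (default `FALSE`).
#' @return A `dissim_matrix` of kind `"behavioral_rating"` with
#'   `value_range = c(1, 9)` and `NA` diagonal (identical pairs are not
#'   presented).
#' @export
aggregate_ratings <- function(table, items, symmetrize = FALSE) {
  stopifnot(all(c("item_first", "item_second", "rating") %in%
                  names(table)))
  n <- length(items)
  sums <- matrix(0, n, n, dimnames = list(items, items))
  cnts <- matrix(0L, n, n)
  i <- match(table$item_first, items)
  j <- match(table$item_second, items)
  if (any(is.na(i)) || any(is.na(j))) {
    stop("rating table contains unknown items", call. = FALSE)
  }
  cell <- (j - 1L) * n + i
  s <- rowsum(as.numeric(table$rating), cell)
  sums[as.integer(rownames(s))] <- s
  cn <- table(cell)
  cnts[as.integer(names(cn))] <- as.integer(cn)
  off <- which(cnts == 0L & !diag(n), arr.ind = TRUE)
  if (nrow(off) > 0L) {
    pairs <- paste0("(", items[off[, 1]], ", ", items[off[, 2]], ")")
    stop("uncovered item pairs: ",
         paste(utils::head(pairs, 10), collapse = ", "),
         if (nrow(off) > 10) " ...", call. = FALSE)
  }
  M <- sums / ifelse(cnts > 0L, cnts, NA_integer_)
  if (symmetrize) M <- (M + t(M)) / 2
  dissim_matrix(M, items, kind = "behavioral_rating",
                value_range = c(1, 9))
}

#' Which instrument rendering to play for a stimulus pair
#'
#' For a vocal-instrument pair the instrument plays the vowel's matched
#' equal-tempered note; any other pair involving an instrument uses the
#' default note (E3). Pairs without an instrument pass through unchanged.
#'
#' @param item_i,item_j Item labels.
#' @param set A `stimulus_set`.
#' @return The note name to render the instrument(s) at, or `NA` if the
#'   rule does not apply.
#' @export
pairing_note_rule <- function(item_i, item_j, set) {
  stopifnot(inherits(set, "stimulus_set"))
  cat_of <- function(it) {
    if (!it %in% names(set$clips)) stop("unknown item: ", it,
                                        call. = FALSE)
    set$clips[[it]]$category
  }
  ci <- cat_of(item_i); cj <- cat_of(item_j)
  if (ci != "instrument" && cj != "instrument") return(NA_character_)
  if (ci == "vocal") return(set$note_table[[item_i]])
  if (cj == "vocal") return(set$note_table[[item_j]])
  set$default_note
}

#' Extract a within- or between-category subset of item pairs
#'
#' Within-category subsets (`category_a == category_b`) return the
#' unordered pairs i < j; between-category subsets return every (row in a,
#' column in b) cell.
#'
#' @param matrix A `dissim_matrix` with `categories` set.
#' @param category_a,category_b Category labels, or `"all"` for every
#'   unordered pair.
#' @return A data frame with columns `i`, `j` (indices into `items`) and
#'   `value`.
#' @export
subset_vector <- function(matrix, category_a, category_b = category_a) {
  stopifnot(inherits(matrix, "dissim_matrix"))
  idx <- subset_pairs(matrix$categories, category_a, category_b)
  data.frame(i = idx[, 1], j = idx[, 2],
             value = matrix$values[idx])
}

#' Index pairs for a category subset
#'
#' @param categories Per-item category vector.
#' @inheritParams subset_vector
#' @return Two-column integer matrix of (row, column) indices.
#' @export
subset_pairs <- function(categories, category_a, category_b = category_a) {
  n <- length(categories)
  if (identical(category_a, "all")) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(unname(idx[, c(1, 2), drop = FALSE]))
  }
  ia <- which(categories == category_a)
  ib <- which(categories == category_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("empty subset: no items in category '",
         if (length(ia) == 0L) category_a else category_b, "'",
         call. = FALSE)
  }
  if (identical(category_a, category_b)) {
    cmb <- t(utils::combn(ia, 2L))
    return(cmb)
  }
  as.matrix(expand.grid(i = ia, j = ib, KEEP.OUT.ATTRS = FALSE))
}
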