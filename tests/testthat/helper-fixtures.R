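# Shared fixtures. The default stimulus set and its feature table are
# expensive (~10 s), so they are built once per test run on first use.

.fixtures <- new.env(parent = emptyenv())

default_set <- function() {
  if (is.null(.fixtures$set)) {
    .fixtures$set <- standardize_set(build_stimulus_set(seed = 1))
  }
  .fixtures$set
}

default_features <- function() {
  if (is.null(.fixtures$features)) {
    .fixtures$features <- feature_table(default_set())
  }
  .fixtures$features
}

make_clip <- function(x, sr = 44100, ...) {
  audio_clip(x / max(abs(x)) * 0.5, sr, ...)
}

tone_clip <- function(freq, dur = 0.25, sr = 44100, ...) {
  make_clip(sin(2 * pi * freq * seq_len(round(dur * sr)) / sr), sr,
            category = "instrument", ...)
}

noise_clip <- function(dur = 0.25, sr = 44100, seed = 1, ...) {
  set.seed(seed)
  make_clip(stats::rnorm(round(dur * sr)), sr,
            category = "environmental", ...)
}

harmonic_clip <- function(f0, n_harm = 10, dur = 0.25, sr = 44100,
                          amp = NULL, ...) {
  t <- seq_len(round(dur * sr)) / sr
  a <- amp %||% (1 / seq_len(n_harm))
  x <- rowSums(sapply(seq_len(n_harm),
                      function(k) a[k] * sin(2 * pi * f0 * k * t)))
  make_clip(x, sr, category = "instrument", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) brute-force Kendall tau-b oracle: explicit pair counting with tie
# corrections, independent of the package's merge-sort implementation
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# hand Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# tiny hand-built feature table for dissimilarity/RSA unit tests
toy_feature_table <- function(scalars, vectors = NULL, mps = NULL,
                              categories = NULL) {
  items <- rownames(scalars) %||% paste0("it", seq_len(nrow(scalars)))
  n <- length(items)
  cats <- categories %||% rep("environmental", n)
  sc <- data.frame(label = items, category = cats,
                   subcategory = cats, stringsAsFactors = FALSE)
  for (nm in scalar_feature_names()) {
    sc[[nm]] <- if (nm %in% colnames(scalars)) scalars[, nm] else
      seq_len(n)
  }
  vm <- vectors %||% matrix(seq_len(2 * n), n, 2)
  mm <- mps %||% matrix(seq_len(3 * n), n, 3)
  rownames(vm) <- rownames(mm) <- items
  structure(
    list(scalars = sc, cochleagram_median = vm, cochleagram_iqr = vm,
         mps = mm, items = items, categories = cats,
         subcategories = cats),
    class = "feature_table")
}
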