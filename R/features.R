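# Per-stimulus feature summarization: scalar descriptors are median/IQR
# over analysis frames; spectral variability and aperiodicity keep only the
# median (they are already variability measures); cochleagram channels are
# summarized per channel; the modulation power spectrum is kept whole.

#' Names of the scalar acoustic features
#'
#' @return Character vector of the scalar feature columns produced by
#'   [summarize_clip()].
#' @export
scalar_feature_names <- function() {
  c("log_attack_time", "temporal_centroid",
    "spectral_centroid_median", "spectral_centroid_iqr",
    "spectral_flatness_median", "spectral_flatness_iqr",
    "spectral_variability_median", "aperiodicity_median",
    "f0_median", "f0_iqr")
}

#' Summarize a standardized clip into a feature row
#'
#' Runs the full descriptor suite ([erb_cochleagram()],
#' [spectral_frame_stats()], [spectral_variability()], [yin_track()],
#' [temporal_features()], [modulation_power_spectrum()]) and aggregates
#' frame-level values to medians and inter-quartile ranges.
#'
#' @param clip A standardized [audio_clip].
#' @param n_channels,fmin,fmax,frame_rate Passed to [erb_cochleagram()].
#' @param mps_params List of arguments for [modulation_power_spectrum()].
#' @return A list of class `feature_row` with the scalar features of
#'   [scalar_feature_names()], `cochleagram_median` and `cochleagram_iqr`
#'   (vectors over channels), and `mps`.
#' @export
summarize_clip <- function(clip, n_channels = 77, fmin = 30, fmax = 16000,
                           frame_rate = 200, mps_params = list()) {
  stopifnot(inherits(clip, "audio_clip"))
  if (max(abs(clip$samples)) == 0) stop("silent clip", call. = FALSE)
  coch <- erb_cochleagram(clip, n_channels = n_channels, fmin = fmin,
                          fmax = fmax, frame_rate = frame_rate)
  stats_f <- spectral_frame_stats(coch)
  sv <- spectral_variability(coch)
  yin <- yin_track(clip)
  tf <- temporal_features(clip)
  mps <- do.call(modulation_power_spectrum, c(list(clip), mps_params))
  iqr <- function(v) unname(stats::quantile(v, 0.75, na.rm = TRUE) -
                              stats::quantile(v, 0.25, na.rm = TRUE))
  structure(list(
    label = clip$label, category = clip$category,
    subcategory = clip$subcategory,
    log_attack_time = tf$log_attack_time,
    temporal_centroid = tf$temporal_centroid,
    spectral_centroid_median = stats::median(stats_f$centroid,
                                             na.rm = TRUE),
    spectral_centroid_iqr = iqr(stats_f$centroid),
    spectral_flatness_median = stats::median(stats_f$flatness,
                                             na.rm = TRUE),
    spectral_flatness_iqr = iqr(stats_f$flatness),
    spectral_variability_median = sv$median,
    aperiodicity_median = stats::median(yin$aperiodicity),
    f0_median = stats::median(yin$f0),
    f0_iqr = iqr(yin$f0),
    cochleagram_median = apply(coch$energy, 1, stats::median),
    cochleagram_iqr = apply(coch$energy, 1, iqr),
    mps = mps), class = "feature_row")
}

#' Extract a feature table for a stimulus set
#'
#' Summarizes the 36 base clips (instruments at the default-note rendering,
#' matching the convention of analyzing instrument features at E3).
#'
#' @param set A standardized `stimulus_set` (see [standardize_set()]).
#' @param progress Print a dot per clip.
#' @inheritParams summarize_clip
#' @return An object of class `feature_table`: a list with `scalars` (data
#'   frame, one row per item), `cochleagram_median` and `cochleagram_iqr`
#'   (item x channel matrices), `mps` (item x flattened-dB matrix), and
#'   `items`, `categories`, `subcategories`.
#' @export
feature_table <- function(set, progress = FALSE, n_channels = 77,
                          fmin = 30, fmax = 16000, frame_rate = 200,
                          mps_params = list()) {
  stopifnot(inherits(set, "stimulus_set"))
  rows <- lapply(set$clips, function(cl) {
    if (progress) cat(".")
    summarize_clip(cl, n_channels = n_channels, fmin = fmin, fmax = fmax,
                   frame_rate = frame_rate, mps_params = mps_params)
  })
  if (progress) cat("\n")
  feature_table_from_rows(rows)
}

#' Assemble a feature table from a list of feature rows
#'
#' @param rows List of `feature_row` objects.
#' @return A `feature_table`.
#' @export
feature_table_from_rows <- function(rows) {
  items <- vapply(rows, `[[`, "", "label")
  scalars <- data.frame(
    label = items,
    category = vapply(rows, `[[`, "", "category"),
    subcategory = vapply(rows, `[[`, "", "subcategory"),
    row.names = NULL, stringsAsFactors = FALSE)
  for (nm in scalar_feature_names()) {
    scalars[[nm]] <- vapply(rows, `[[`, 0, nm)
  }
  cm <- t(vapply(rows, `[[`, rows[[1]]$cochleagram_median,
                 "cochleagram_median"))
  ci <- t(vapply(rows, `[[`, rows[[1]]$cochleagram_iqr,
                 "cochleagram_iqr"))
  mps0 <- .mps_vector(rows[[1]]$mps)
  mp <- t(vapply(rows, function(r) .mps_vector(r$mps), mps0))
  rownames(cm) <- rownames(ci) <- rownames(mp) <- items
  structure(
    list(scalars = scalars, cochleagram_median = cm, cochleagram_iqr = ci,
         mps = mp, items = items, categories = scalars$category,
         subcategories = scalars$subcategory),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d items, %d scalar features, %d-channel ",
              length(x$items), length(scalar_feature_names()),
              ncol(x$cochleagram_median)))
  cat(sprintf("cochleagram, MPS length %d\n", ncol(x$mps)))
  invisible(x)
}

#' Names of the features entering item-pair dissimilarity analyses
#'
#' The eleven base RSA features (scalar differences plus Euclidean
#' distances on the cochleagram summaries and the modulation power
#' spectrum) and, where the inclusion rule allows, the two F0 features.
#'
#' @param include_f0 `"none"`, `"iqr"`, or `"both"`.
#' @return Character vector of feature names.
#' @export
rsa_feature_names <- function(include_f0 = c("none", "iqr", "both")) {
  include_f0 <- match.arg(include_f0)
  base <- c("aperiodicity_median", "cochleagram_iqr", "cochleagram_median",
            "mps", "log_attack_time", "spectral_centroid_iqr",
            "spectral_centroid_median", "spectral_flatness_iqr",
            "spectral_flatness_median", "spectral_variability_median",
            "temporal_centroid")
  switch(include_f0,
         none = base,
         iqr = c(base, "f0_iqr"),
         both = c(base, "f0_iqr", "f0_median"))
}
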