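# Stimulus standardization: onset detection on a high-passed copy, trim to
# a fixed duration from onset, raised-cosine ramps, RMS normalization.

#' Preprocessing configuration
#'
#' @param onset_fraction Fraction of the filtered signal's maximum absolute
#'   amplitude that defines the onset (default 0.10).
#' @param highpass_cutoff High-pass cutoff in Hz for the onset-detection
#'   copy (default 20).
#' @param target_duration Output duration in seconds (default 0.250).
#' @param ramp_duration Cosine ramp duration in seconds (default 0.005).
#' @param target_rms RMS level of the output in full scale (default 0.05).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(onset_fraction = 0.10, highpass_cutoff = 20,
                              target_duration = 0.250,
                              ramp_duration = 0.005, target_rms = 0.05) {
  stopifnot(onset_fraction > 0, onset_fraction < 1,
            2 * ramp_duration < target_duration, target_rms > 0)
  structure(list(onset_fraction = onset_fraction,
                 highpass_cutoff = highpass_cutoff,
                 target_duration = target_duration,
                 ramp_duration = ramp_duration,
                 target_rms = target_rms),
            class = "preprocess_config")
}

.onset_filter <- function(samples, sample_rate, cutoff) {
  # 2nd-order design run forward and backward: zero-phase with a 4th-order
  # magnitude response
  bf <- signal::butter(2, cutoff / (sample_rate / 2), "high")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Detect the onset of a clip
#'
#' The onset is the first sample at which the absolute amplitude of a
#' high-pass filtered copy of the signal (zero-phase Butterworth) strictly
#' exceeds `onset_fraction` times that copy's maximum absolute amplitude.
#' The filtered copy is used only for detection, never for output samples.
#'
#' @param clip An [audio_clip].
#' @param config A [preprocess_config()].
#' @param filter If `FALSE`, skip the high-pass stage (useful for tests on
#'   constructed signals).
#' @return The onset sample index (1-based).
#' @export
detect_onset <- function(clip, config = preprocess_config(),
                         filter = TRUE) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (max(abs(x)) == 0) stop("silent clip", call. = FALSE)
  f <- if (filter) {
    .onset_filter(x, clip$sample_rate, config$highpass_cutoff)
  } else x
  thr <- config$onset_fraction * max(abs(f))
  idx <- which(abs(f) > thr)
  if (length(idx) == 0L) stop("no onset found", call. = FALSE)
  idx[1L]
}

#' Standardize a clip: trim from onset, ramp, normalize
#'
#' Trims the unfiltered waveform to `target_duration` starting at the
#' detected onset, applies raised-cosine onset/offset ramps, and normalizes
#' the result to `target_rms`.
#'
#' @inheritParams detect_onset
#' @return A standardized [audio_clip] of exactly
#'   `round(target_duration * sample_rate)` samples.
#' @export
standardize_clip <- function(clip, config = preprocess_config(),
                             filter = TRUE) {
  onset <- detect_onset(clip, config, filter = filter)
  sr <- clip$sample_rate
  n_out <- round(config$target_duration * sr)
  if (onset + n_out - 1L > length(clip$samples)) {
    stop("insufficient material after onset in '", clip$label, "' (need ",
         n_out, " samples, have ", length(clip$samples) - onset + 1L, ")",
         call. = FALSE)
  }
  y <- clip$samples[onset:(onset + n_out - 1L)]
  n_ramp <- round(config$ramp_duration * sr)
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_ramp)))
    y[seq_len(n_ramp)] <- y[seq_len(n_ramp)] * ramp
    y[(n_out - n_ramp + 1L):n_out] <- y[(n_out - n_ramp + 1L):n_out] *
      rev(ramp)
  }
  rms <- sqrt(mean(y^2))
  if (rms == 0) stop("clip is silent after trimming", call. = FALSE)
  y <- y * config$target_rms / rms
  out <- clip
  out$samples <- y
  out
}

#' Standardize every clip of a stimulus set
#'
#' Applies [standardize_clip()] to the 36 base clips and all instrument
#' renderings.
#'
#' @param set A `stimulus_set`.
#' @param config A [preprocess_config()].
#' @return The set with all clips standardized.
#' @export
standardize_set <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "stimulus_set"))
  set$clips <- lapply(set$clips, standardize_clip, config = config)
  set$renderings <- lapply(set$renderings, function(per_note) {
    lapply(per_note, standardize_clip, config = config)
  })
  set$standardized <- TRUE
  set
}
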