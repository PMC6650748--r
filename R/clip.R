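#' Audio clip container
#'
#' A lightweight S3 container for a mono waveform with the labels the rest of
#' the pipeline needs: a text identifier, a superordinate category (vocal,
#' instrument, environmental), a subcategory (vowel identity, instrument
#' family, or excitation medium), and -- for periodic sources -- the nominal
#' fundamental frequency and its equal-tempered note name.
#'
#' @param samples Numeric vector of amplitudes in full scale (all |x| <= 1).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param label Text identifier.
#' @param category One of `"vocal"`, `"instrument"`, `"environmental"`.
#' @param subcategory Vowel identity, instrument family, or excitation medium.
#' @param nominal_f0 Nominal fundamental in Hz, or `NA` (environmental only).
#' @param note_name Matched equal-tempered note, or `NA`.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate, label = "clip",
                       category = c("vocal", "instrument", "environmental"),
                       subcategory = NA_character_,
                       nominal_f0 = NA_real_, note_name = NA_character_) {
  category <- match.arg(category)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive", call. = FALSE)
  }
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("samples exceed full scale (|x| > 1)", call. = FALSE)
  }
  if (category != "environmental" && is.na(nominal_f0) &&
      !is.na(note_name)) {
    nominal_f0 <- note_to_frequency(note_name)
  }
  structure(
    list(samples = samples, sample_rate = sample_rate, label = label,
         category = category, subcategory = subcategory,
         nominal_f0 = nominal_f0, note_name = note_name),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s [%s/%s] %.0f Hz, %.1f ms%s\n",
              x$label, x$category, x$subcategory, x$sample_rate,
              1000 * length(x$samples) / x$sample_rate,
              if (is.na(x$nominal_f0)) "" else
                sprintf(", f0 %.2f Hz (%s)", x$nominal_f0, x$note_name)))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

.clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

.clip_rms <- function(clip) sqrt(mean(clip$samples^2))
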