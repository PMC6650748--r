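# ERB-spaced gammatone cochleagram. Filtering is done in the frequency
# domain: each channel's analytic band signal is obtained by multiplying the
# one-sided spectrum with a 4th-order gammatone magnitude response, and the
# channel envelope is the magnitude of the inverse transform.

#' ERB scale helpers (Glasberg--Moore)
#'
#' `erb_bandwidth(f)` returns the equivalent rectangular bandwidth
#' `24.7 * (4.37 * f / 1000 + 1)` in Hz; `erb_rate(f)` and `erb_rate_inv(E)`
#' convert between frequency and ERB-number.
#'
#' @param f Frequency in Hz.
#' @return Bandwidth in Hz, or ERB number.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' @rdname erb_bandwidth
#' @export
erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname erb_bandwidth
#' @param E ERB number.
#' @export
erb_rate_inv <- function(E) (10^(E / 21.4) - 1) * 1000 / 4.37

#' Compute an ERB/gammatone cochleagram
#'
#' `n_channels` gammatone filters with ERB-rate-spaced center frequencies
#' between `fmin` and `fmax`. Filtering is frequency-domain (4th-order
#' gammatone magnitude response applied to the analytic spectrum), with
#' channel gains normalized for equal broadband-noise response so that the
#' channel profile of white noise is approximately flat. The per-channel
#' envelope (magnitude of the analytic band signal) is averaged within
#' non-overlapping frames at `frame_rate`.
#'
#' @param clip An [audio_clip].
#' @param n_channels Number of channels (default 77).
#' @param fmin,fmax Lowest and highest center frequency in Hz (defaults 30
#'   and 16000; `fmax` must be below Nyquist).
#' @param frame_rate Envelope frame rate in Hz (default 200).
#' @return A list of class `cochleagram` with `energy` (channels x frames,
#'   linear envelope), `center_frequencies`, `frame_times`.
#' @export
erb_cochleagram <- function(clip, n_channels = 77, fmin = 30, fmax = 16000,
                            frame_rate = 200) {
  stopifnot(inherits(clip, "audio_clip"))
  sr <- clip$sample_rate
  if (fmax >= sr / 2) {
    stop("fmax must be below the Nyquist frequency", call. = FALSE)
  }
  x <- clip$samples
  n <- length(x)
  cf <- erb_rate_inv(seq(erb_rate(fmin), erb_rate(fmax),
                         length.out = n_channels))
  nfft <- 2^ceiling(log2(n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  freqs <- (seq_len(nfft) - 1) * sr / nfft
  # one-sided (analytic) spectrum
  Xa <- X
  pos <- freqs > 0 & freqs < sr / 2
  Xa[pos] <- 2 * Xa[pos]
  Xa[freqs >= sr / 2] <- 0

  hop <- round(sr / frame_rate)
  n_frames <- floor(n / hop)
  energy <- matrix(0, n_channels, n_frames)
  frame_idx <- rep(seq_len(n_frames), each = hop)
  for (c_i in seq_len(n_channels)) {
    b <- 1.019 * erb_bandwidth(cf[c_i])
    H <- (1 + ((freqs - cf[c_i]) / b)^2)^(-2)
    # equal broadband-noise response across channels, so white noise gives
    # an approximately flat channel profile (cf. FFT spectral flatness)
    H <- H / sqrt(sum(H^2))
    band <- stats::fft(Xa * H, inverse = TRUE)[seq_len(n)] / nfft
    env <- Mod(band)
    energy[c_i, ] <- tapply(env[seq_len(n_frames * hop)], frame_idx, mean)
  }
  structure(
    list(energy = energy, center_frequencies = cf,
         frame_times = (seq_len(n_frames) - 0.5) * hop / sr),
    class = "cochleagram")
}

#' Per-frame spectral centroid and flatness of a cochleagram
#'
#' Centroid is the energy-weighted mean of the channel center frequencies;
#' flatness is the ratio of geometric to arithmetic mean of the channel
#' envelope (with a floor of `eps` per channel to avoid log(0)). Frames
#' with zero total energy yield `NA` and are excluded from summaries.
#'
#' @param coch A [erb_cochleagram()] result.
#' @param eps Flatness floor (default 1e-12).
#' @return A data frame with per-frame `centroid` (Hz) and `flatness`
#'   (0--1).
#' @export
spectral_frame_stats <- function(coch, eps = 1e-12) {
  stopifnot(inherits(coch, "cochleagram"))
  E <- coch$energy
  cf <- coch$center_frequencies
  tot <- colSums(E)
  centroid <- ifelse(tot > 0, colSums(E * cf) / tot, NA_real_)
  Ef <- E + eps
  flatness <- exp(colMeans(log(Ef))) / colMeans(Ef)
  flatness[tot == 0] <- NA_real_
  data.frame(centroid = centroid, flatness = flatness)
}

#' Spectral variability of a cochleagram
#'
#' One minus the Pearson correlation of the channel spectra between
#' successive frames. Steps involving a constant (zero-variance) frame are
#' skipped.
#'
#' @param coch A [erb_cochleagram()] result with at least two frames.
#' @return A list with per-step `values` (0--2) and their `median`.
#' @export
spectral_variability <- function(coch) {
  stopifnot(inherits(coch, "cochleagram"))
  E <- coch$energy
  n_frames <- ncol(E)
  if (n_frames < 2L) stop("need at least 2 frames", call. = FALSE)
  sds <- apply(E, 2, stats::sd)
  vals <- rep(NA_real_, n_frames - 1L)
  for (t_i in seq_len(n_frames - 1L)) {
    if (sds[t_i] > 0 && sds[t_i + 1L] > 0) {
      vals[t_i] <- 1 - stats::cor(E[, t_i], E[, t_i + 1L])
    }
  }
  vals <- vals[!is.na(vals)]
  list(values = vals, median = stats::median(vals))
}
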