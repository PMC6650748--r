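# Modulation power spectrum: 2-D Fourier transform of a Gaussian-window
# log-magnitude spectrogram limited to a 50 dB dynamic range.

#' Modulation power spectrum of a clip
#'
#' A Gaussian-window spectrogram is computed on a time/frequency grid whose
#' sampling fixes the modulation Nyquist limits: the frame hop is
#' `1 / (2 * temporal_max)` seconds and the frequency-bin spacing is
#' `1 / (2 * spectral_max / 1000)` Hz, so the temporal-modulation axis
#' extends to `temporal_max` Hz and the spectral-modulation axis to
#' `spectral_max` cyc/kHz (defaults 47.92 Hz and 31.24 cyc/kHz). The
#' log-magnitude spectrogram is clipped to its top `dynamic_range` dB and
#' transformed by a 2-D FFT; squared magnitude is retained, with the
#' spectral-modulation axis folded to non-negative values.
#'
#' @param clip A standardized (fixed-length) [audio_clip].
#' @param temporal_max Temporal-modulation Nyquist in Hz (default 47.92).
#' @param spectral_max Spectral-modulation Nyquist in cyc/kHz (default
#'   31.24).
#' @param sigma_scale Gaussian window sigma as a multiple of the hop
#'   (default 1; window length is 6 sigma).
#' @param dynamic_range Spectrogram dynamic range in dB (default 50).
#' @return A list of class `modulation_power_spectrum` with `power`
#'   (spectral x temporal modulation), `spectral_axis` (cyc/kHz, >= 0) and
#'   `temporal_axis` (Hz, symmetric about 0).
#' @export
modulation_power_spectrum <- function(clip, temporal_max = 47.92,
                                      spectral_max = 31.24,
                                      sigma_scale = 1,
                                      dynamic_range = 50) {
  stopifnot(inherits(clip, "audio_clip"))
  sr <- clip$sample_rate
  x <- clip$samples
  hop <- round(sr / (2 * temporal_max))            # temporal sampling
  nfft <- round(sr / (1 / (2 * spectral_max / 1000)))
  df <- sr / nfft                                  # realized bin spacing
  sigma <- sigma_scale * hop
  half_w <- min(round(3 * sigma), (nfft - 1L) %/% 2L)
  win_len <- 2L * half_w + 1L
  win <- exp(-0.5 * ((seq_len(win_len) - half_w - 1) / sigma)^2)

  centers <- seq(1L, length(x), by = hop)
  xp <- c(numeric(half_w), x, numeric(half_w))
  n_bins <- nfft %/% 2L + 1L
  S <- matrix(0, n_bins, length(centers))
  for (fi in seq_along(centers)) {
    seg <- xp[centers[fi]:(centers[fi] + win_len - 1L)] * win
    sp <- stats::fft(c(seg, numeric(nfft - win_len)))
    S[, fi] <- Mod(sp[seq_len(n_bins)])
  }
  SdB <- 20 * log10(S + 1e-12)
  SdB <- pmax(SdB, max(SdB) - dynamic_range)

  M <- stats::fft(SdB)                              # 2-D FFT (freq x time)
  P <- Mod(M)^2
  # axes: spectral modulation in cyc/Hz -> cyc/kHz; temporal in Hz
  n_t <- ncol(P)
  spec_axis <- (seq_len(n_bins) - 1) / (n_bins * df) * 1000
  spec_keep <- spec_axis <= spectral_max + 1e-9
  t_idx <- seq_len(n_t) - 1
  t_axis <- ifelse(t_idx <= n_t / 2, t_idx, t_idx - n_t) /
    (n_t * hop / sr)
  ord <- order(t_axis)
  structure(
    list(power = P[spec_keep, ord, drop = FALSE],
         spectral_axis = spec_axis[spec_keep],
         temporal_axis = t_axis[ord]),
    class = "modulation_power_spectrum")
}

# flattened dB-scale representation used for item-pair distances
.mps_vector <- function(mps, eps = 1e-20) {
  as.numeric(10 * log10(mps$power + eps))
}
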