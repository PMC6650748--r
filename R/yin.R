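# YIN fundamental-frequency and aperiodicity estimation: cumulative
# mean-normalized difference function per frame, first dip under threshold
# with parabolic interpolation; the dip depth is the aperiodicity measure.

#' Track fundamental frequency and aperiodicity with YIN
#'
#' For each analysis frame the squared difference function
#' `d(tau) = sum_j (x_j - x_{j+tau})^2` is computed (via FFT correlation),
#' normalized to the cumulative-mean form `d'(tau)`, and searched over the
#' lag range corresponding to `fmin_search`--`fmax_search`. The estimate is
#' the first local dip of `d'` under `threshold` (with parabolic
#' interpolation); if no dip falls under the threshold the global minimum
#' is used. Aperiodicity is the `d'` value at the chosen dip, bounded to
#' [0, 1]; aperiodic signals have shallow dips and erratic lag estimates.
#'
#' @param clip An [audio_clip].
#' @param fmin_search,fmax_search F0 search range in Hz (defaults 60 and
#'   800).
#' @param window Analysis window in seconds (default 0.025; must span at
#'   least two periods of `fmin_search`).
#' @param hop Hop between frames in seconds (default 0.005).
#' @param threshold Dip threshold on the normalized difference function
#'   (default 0.1).
#' @return A data frame with per-frame `time`, `f0` (Hz) and `aperiodicity`
#'   (0--1).
#' @export
yin_track <- function(clip, fmin_search = 60, fmax_search = 800,
                      window = 0.025, hop = 0.005, threshold = 0.1) {
  stopifnot(inherits(clip, "audio_clip"))
  sr <- clip$sample_rate
  W <- round(window * sr)
  if (W < sr / fmin_search) {
    # the difference function needs at least one full period of the lowest
    # search frequency inside the correlation window
    stop("window must span at least one period of fmin_search",
         call. = FALSE)
  }
  tau_min <- max(2L, floor(sr / fmax_search))
  tau_max <- ceiling(sr / fmin_search)
  span <- W + tau_max
  x <- clip$samples
  if (length(x) < span) {
    stop("clip shorter than one analysis window", call. = FALSE)
  }
  hop_n <- max(1L, round(hop * sr))
  starts <- seq(1L, length(x) - span + 1L, by = hop_n)
  nfft <- 2^ceiling(log2(2L * span))

  f0 <- ap <- numeric(length(starts))
  for (fi in seq_along(starts)) {
    seg <- x[starts[fi]:(starts[fi] + span - 1L)]
    # d(tau) = r0 + r_tau - 2*acf(tau) over j = 1..W
    cs <- cumsum(seg^2)
    r0 <- cs[W]
    r_tau <- cs[W + 0:tau_max] - c(0, cs[0:tau_max])[1:(tau_max + 1L)]
    Fa <- stats::fft(c(seg[1:W], numeric(nfft - W)))
    Fb <- stats::fft(c(seg, numeric(nfft - span)))
    cc <- Re(stats::fft(Conj(Fa) * Fb, inverse = TRUE)) / nfft
    acf_tau <- cc[1:(tau_max + 1L)]
    d <- r0 + r_tau - 2 * acf_tau          # index t+1 holds lag t
    d[d < 0] <- 0
    # cumulative mean normalization
    dn <- d
    dn[1L] <- 1
    csum <- cumsum(d[-1L])
    dn[-1L] <- d[-1L] * seq_len(tau_max) / pmax(csum, 1e-30)

    lags <- tau_min:tau_max
    v <- dn[lags + 1L]
    below <- which(v < threshold)
    if (length(below) > 0L) {
      k <- below[1L]
      while (k < length(v) && v[k + 1L] < v[k]) k <- k + 1L
    } else {
      k <- which.min(v)
    }
    tau <- lags[k]
    # parabolic interpolation on the normalized difference function
    if (tau > tau_min && tau < tau_max) {
      y0 <- dn[tau]; y1 <- dn[tau + 1L]; y2 <- dn[tau + 2L]
      denom <- y0 - 2 * y1 + y2
      shift <- if (abs(denom) > 1e-30) 0.5 * (y0 - y2) / denom else 0
      shift <- max(-1, min(1, shift))
      tau_hat <- tau + shift
      dip <- y1 - 0.25 * (y0 - y2) * shift
    } else {
      tau_hat <- tau
      dip <- dn[tau + 1L]
    }
    f0[fi] <- sr / tau_hat
    ap[fi] <- max(0, min(1, dip))
  }
  data.frame(time = (starts - 1L + W / 2) / sr, f0 = f0, aperiodicity = ap)
}
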