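# Temporal-envelope descriptors: log-attack-time and temporal centroid.

#' Log-attack-time and temporal centroid
#'
#' The amplitude envelope is short-frame RMS (5 ms windows, 1 ms hop).
#' Attack onset and end are the first crossings of 10% and 90% of the
#' envelope maximum; log-attack-time is the base-10 log of their time
#' difference (floored at one hop when the attack is effectively
#' instantaneous). The temporal centroid is the envelope's center of
#' gravity, `sum(t * env) / sum(env)`.
#'
#' @param clip A non-silent [audio_clip].
#' @param frame Envelope RMS window in seconds (default 0.005).
#' @param hop Envelope hop in seconds (default 0.001).
#' @return A list with `log_attack_time` (log10 s), `temporal_centroid`
#'   (s), and the `envelope` (data frame of `time`, `value`).
#' @export
temporal_features <- function(clip, frame = 0.005, hop = 0.001) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  if (max(abs(x)) == 0) stop("silent clip", call. = FALSE)
  sr <- clip$sample_rate
  w <- max(1L, round(frame * sr))
  h <- max(1L, round(hop * sr))
  starts <- seq(1L, length(x) - w + 1L, by = h)
  cs2 <- c(0, cumsum(x^2))
  env <- sqrt((cs2[starts + w] - cs2[starts]) / w)
  tt <- (starts - 1L + w / 2) / sr

  m <- max(env)
  t10 <- tt[which(env > 0.1 * m)[1L]]
  t90 <- tt[which(env > 0.9 * m)[1L]]
  attack <- max(t90 - t10, hop)
  centroid <- sum(tt * env) / sum(env)
  list(log_attack_time = log10(attack), temporal_centroid = centroid,
       envelope = data.frame(time = tt, value = env))
}
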