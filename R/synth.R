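# Synthetic 36-item stimulus set: 12 vowel utterances (6 simulated speakers x
# 2 vowels), 12 harmonic instrument-like tones, and 12 noise-dominated
# environmental tokens spanning 6 excitation media. The point of the set is
# the category-level acoustic contrasts (periodicity, spectral envelope,
# temporal envelope, spectrotemporal variability), not perceptual realism.

.formant_presets <- list(
  "a" = list(F = c(710, 1100), B = c(90, 110)),
  "i" = list(F = c(280, 2250), B = c(60, 100)))

.resonator <- function(x, f, bw, sr) {
  # two-pole resonator with unit gain at the resonant frequency
  r <- exp(-pi * bw / sr)
  theta <- 2 * pi * f / sr
  a <- c(1, -2 * r * cos(theta), r^2)
  b <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
  as.numeric(signal::filter(b, a, x))
}

.one_pole_lp <- function(x, coef) {
  as.numeric(signal::filter(1 - coef, c(1, -coef), x))
}

.fade_in <- function(x, sr, ms) {
  n <- min(length(x), round(sr * ms / 1000))
  if (n > 1) x[seq_len(n)] <- x[seq_len(n)] * seq(0, 1, length.out = n)
  x
}

.lead_silence <- function(x, sr, ms = 10) {
  c(numeric(round(sr * ms / 1000)), x)
}

.peak_normalize <- function(x, peak = 0.9) {
  m <- max(abs(x))
  if (m > 0) x * peak / m else x
}

#' Synthesize a vowel-like periodic sound
#'
#' A jittered glottal pulse train with a spectral-tilt lowpass is passed
#' through a two-resonator formant cascade. The /a/ and /i/ presets use
#' canonical formant values (/a/: F1 710, F2 1100 Hz; /i/: F1 280, F2 2250
#' Hz); individual "speakers" differ by a formant scaling factor and glottal
#' tilt coefficient.
#'
#' @param f0 Fundamental frequency in Hz (60--400).
#' @param vowel `"a"` or `"i"`.
#' @param duration Duration in seconds (default 0.3, leaving material for
#'   onset trimming).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed controlling jitter and aspiration noise.
#' @param formant_scale Multiplier on the formant frequencies (vocal-tract
#'   length proxy; default 1).
#' @param tilt One-pole glottal lowpass coefficient in (0, 1); higher values
#'   give steeper spectral rolloff.
#' @param jitter Per-period relative F0 jitter SD (default 0.003).
#' @param aspiration Breathiness: amplitude of aspiration noise relative to
#'   the glottal source (speakers differ; default 0.01).
#' @param label,subcategory Passed to [audio_clip].
#' @return An [audio_clip] with `category = "vocal"`.
#' @export
synth_vowel <- function(f0, vowel = c("a", "i"), duration = 0.3,
                        sample_rate = 44100, seed = 1, formant_scale = 1,
                        tilt = 0.96, jitter = 0.003, aspiration = 0.01,
                        label = NULL, subcategory = NULL) {
  vowel <- match.arg(vowel)
  if (f0 < 60 || f0 > 400) stop("f0 must lie in 60-400 Hz", call. = FALSE)
  set.seed(seed)
  n <- round(duration * sample_rate)
  src <- numeric(n)
  pos <- 1
  while (pos <= n) {
    src[round(pos)] <- 1
    pos <- pos + (sample_rate / f0) * (1 + jitter * stats::rnorm(1))
  }
  # glottal spectral tilt (-12 dB/oct region) + speaker-graded aspiration
  src <- .one_pole_lp(.one_pole_lp(src, tilt), tilt)
  src <- src + aspiration * stats::sd(src) * stats::rnorm(n)
  preset <- .formant_presets[[vowel]]
  y <- src
  for (k in seq_along(preset$F)) {
    y <- .resonator(y, preset$F[k] * formant_scale, preset$B[k], sample_rate)
  }
  y <- .fade_in(y, sample_rate, 15)
  y <- .lead_silence(.peak_normalize(y), sample_rate)
  audio_clip(y, sample_rate,
             label = label %||% sprintf("vowel_%s_%0.0fHz", vowel, f0),
             category = "vocal",
             subcategory = subcategory %||% vowel,
             nominal_f0 = f0,
             note_name = nearest_equal_tempered_note(f0))
}

#' Synthesize a harmonic instrument-like tone
#'
#' Additive harmonic synthesis with an exponential spectral rolloff
#' controlled by `brightness` (harmonic k has amplitude
#' `exp(-(k - 1) / brightness)`) and an amplitude envelope with a linear
#' attack of `attack_ms` followed by exponential decay with time constant
#' `decay`. Deterministic given its arguments.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param attack_ms Attack time in milliseconds (must be shorter than
#'   `duration`).
#' @param brightness Spectral-decay parameter (> 0); larger values put more
#'   energy in high harmonics.
#' @param decay Post-attack exponential decay time constant in seconds
#'   (`Inf` for a sustained tone).
#' @param breath Blowing/bowing noise amplitude relative to the harmonic
#'   part (winds and bowed strings are breathier than plucked strings;
#'   default 0.01). Generated from a fixed internal seed so the tone stays
#'   deterministic given its arguments.
#' @inheritParams synth_vowel
#' @return An [audio_clip] with `category = "instrument"`.
#' @export
synth_instrument <- function(f0, attack_ms = 10, brightness = 3,
                             decay = 0.5, duration = 0.3,
                             sample_rate = 44100, breath = 0.01,
                             label = NULL, subcategory = NULL) {
  if (attack_ms / 1000 >= duration) {
    stop("attack must be shorter than duration", call. = FALSE)
  }
  n <- round(duration * sample_rate)
  t <- seq_len(n) / sample_rate
  n_harm <- max(1L, min(40L, floor(0.45 * sample_rate / f0)))
  k <- seq_len(n_harm)
  amp <- exp(-(k - 1) / brightness)
  # fixed quadratic phase offsets keep the crest factor reasonable
  phase <- 0.7 * k^2
  y <- numeric(n)
  for (j in k) {
    y <- y + amp[j] * sin(2 * pi * f0 * j * t + phase[j])
  }
  if (breath > 0) {
    set.seed(20201L)  # fixed: breath noise must not break determinism
    bf <- signal::butter(2, c(500, min(8000, 0.45 * sample_rate)) /
                           (sample_rate / 2), "pass")
    bn <- as.numeric(signal::filter(bf, stats::rnorm(n)))
    y <- y + breath * stats::sd(y) * bn / stats::sd(bn)
  }
  ta <- attack_ms / 1000
  env <- ifelse(t < ta, t / ta, exp(-(t - ta) / decay))
  y <- .lead_silence(.peak_normalize(y * env), sample_rate)
  audio_clip(y, sample_rate,
             label = label %||% sprintf("instrument_%0.0fHz", f0),
             category = "instrument",
             subcategory = subcategory %||% "instrument",
             nominal_f0 = f0,
             note_name = nearest_equal_tempered_note(f0))
}

#' Synthesize a noise-dominated environmental sound
#'
#' Medium-specific recipes over a Gaussian-noise excitation, following a
#' Gaver-style taxonomy of excitation media: `impact` is an exponentially
#' decaying burst ringing through a few narrow modal resonances; `air` is
#' sustained lowpass noise; `liquid` is sparse decaying chirps over a soft
#' noise bed; `deformation` is gated noise crackle; `mechanical` is
#' amplitude-modulated noise over a frequency-wobbling motor hum (20--60 Hz
#' modulation); `movement` is band-passed noise under a slow random
#' amplitude walk. The resonant/tonal components give the media graded,
#' intermediate aperiodicity (as struck or motor-driven objects have in
#' recordings) but none has a stable fundamental frequency.
#'
#' @param medium One of `"air"`, `"liquid"`, `"deformation"`, `"impact"`,
#'   `"mechanical"`, `"movement"`.
#' @param token Token index within the medium (1 or 2 in the default set);
#'   shifts the recipe parameters so the two tokens differ.
#' @inheritParams synth_vowel
#' @return An [audio_clip] with `category = "environmental"` and
#'   `nominal_f0 = NA`.
#' @export
synth_environmental <- function(medium = c("air", "liquid", "deformation",
                                           "impact", "mechanical",
                                           "movement"),
                                duration = 0.3, sample_rate = 44100,
                                seed = 1, token = 1, label = NULL) {
  medium <- match.arg(medium)
  set.seed(seed)
  n <- round(duration * sample_rate)
  t <- seq_len(n) / sample_rate
  noise <- stats::rnorm(n)
  y <- switch(medium,
    air = {
      cutoff <- c(1200, 2600)[1 + (token - 1) %% 2]
      bf <- signal::butter(2, cutoff / (sample_rate / 2), "low")
      x <- as.numeric(signal::filter(bf, noise))
      # mild slow fluctuation so the level is not perfectly static
      x * (1 + 0.15 * sin(2 * pi * stats::runif(1, 1, 3) * t))
    },
    liquid = {
      bf <- signal::butter(2, 900 / (sample_rate / 2), "low")
      bed <- 0.18 * as.numeric(signal::filter(bf, noise))
      n_drop <- 12 + 4 * token
      for (d in seq_len(n_drop)) {
        # first droplet lands near the start so the trimmed clip opens on
        # a liquid event rather than the faint noise bed
        start <- if (d == 1L) {
          round(stats::runif(1, 0.005, 0.02) * sample_rate)
        } else sample.int(n - 2000, 1)
        len <- round(stats::runif(1, 0.015, 0.04) * sample_rate)
        td <- seq_len(len) / sample_rate
        fstart <- stats::runif(1, 500, 1500)
        glide <- stats::runif(1, 1.5, 3)  # upward chirp, droplet-like
        drop <- sin(2 * pi * fstart * td * (1 + glide * td / max(td))) *
          exp(-td / 0.008)
        idx <- start + seq_len(len) - 1
        bed[idx] <- bed[idx] + stats::runif(1, 0.6, 1.2) * drop
      }
      bed
    },
    deformation = {
      bf <- signal::butter(2, 90 / (sample_rate / 2), "low")
      gate_src <- as.numeric(signal::filter(bf, stats::rnorm(n)))
      thr <- stats::quantile(gate_src, 0.55 + 0.1 * (token - 1))
      gate <- .one_pole_lp(as.numeric(gate_src > thr), 0.995)
      # guarantee an opening crackle so the onset is not left to chance
      burst <- exp(-(seq_len(n) / sample_rate) / 0.01)
      noise * pmax(gate, burst)
    },
    impact = {
      tau <- c(0.035, 0.06)[1 + (token - 1) %% 2]
      # struck objects ring: a few narrow modal resonances over the burst
      modes <- stats::runif(3, 250, 2200)
      body <- Reduce(`+`, lapply(modes, function(fm) {
        .resonator(noise, fm, stats::runif(1, 60, 140), sample_rate)
      }))
      onset <- round(0.012 * sample_rate)
      env <- c(numeric(onset),
               exp(-(seq_len(n - onset) / sample_rate) / tau))
      # plus one coherent ringing partial, as a struck plate or bar has
      ring <- sin(2 * pi * stats::runif(1, 150, 450) * t) *
        exp(-t / (2 * tau))
      (0.35 * noise + 1.0 * body / stats::sd(body) +
         c(1.6, 0.8)[1 + (token - 1) %% 2] * ring) * env
    },
    mechanical = {
      fm <- stats::runif(1, 20, 60)
      bf <- signal::butter(2, c(300, 4000) / (sample_rate / 2), "pass")
      x <- as.numeric(signal::filter(bf, noise))
      # motor hum: a frequency-wobbling low tone under the rattle
      fh <- stats::runif(1, 80, 180)
      wobble <- 0.08 * fh * cumsum(sin(2 * pi * 7 * t)) / sample_rate
      hum <- sin(2 * pi * (fh * t + wobble))
      hum_amp <- c(2.4, 1.2)[1 + (token - 1) %% 2]
      (x / stats::sd(x) + hum_amp * hum) *
        (1 + 0.9 * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi)))
    },
    movement = {
      band <- list(c(500, 1100), c(900, 2000))[[1 + (token - 1) %% 2]]
      bf <- signal::butter(2, band / (sample_rate / 2), "pass")
      x <- as.numeric(signal::filter(bf, noise))
      walk <- .one_pole_lp(cumsum(stats::rnorm(n, sd = 0.02)), 0.999)
      walk <- 0.4 + 0.6 * (walk - min(walk)) / max(1e-12, diff(range(walk)))
      x * walk
    })
  if (medium != "impact") y <- .fade_in(y, sample_rate, 20)
  y <- .lead_silence(.peak_normalize(y), sample_rate, ms = 8)
  audio_clip(y, sample_rate,
             label = label %||% sprintf("%s_%d", medium, token),
             category = "environmental", subcategory = medium)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
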