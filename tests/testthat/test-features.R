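test_that("cochleagram localizes tones and spreads noise", {
  coch <- erb_cochleagram(tone_clip(1000))
  pk <- which.max(rowSums(coch$energy))
  spacing <- diff(coch$center_frequencies)
  expect_lt(abs(coch$center_frequencies[pk] - 1000),
            spacing[min(pk, length(spacing))])
  expect_equal(nrow(coch$energy), 77L)
  expect_true(all(diff(coch$center_frequencies) > 0))
  expect_true(all(coch$energy >= 0))

  silence <- audio_clip(numeric(11025) + 0, 44100,
                        category = "environmental")
  expect_true(all(erb_cochleagram(silence)$energy == 0))

  active <- function(coch) {
    e <- rowSums(coch$energy)
    sum(e > 0.1 * max(e))
  }
  expect_gte(active(erb_cochleagram(noise_clip(seed = 1))),
             10 * active(coch))
  expect_error(erb_cochleagram(tone_clip(1000), fmax = 30000), "Nyquist")
})

test_that("frame stats obey the closed forms on constructed cochleagrams", {
  coch <- structure(list(
    energy = matrix(0, 3, 2), center_frequencies = c(500, 1000, 1500),
    frame_times = c(0.1, 0.2)), class = "cochleagram")
  coch$energy[2, 1] <- 5                      # single active channel
  coch$energy[c(1, 3), 2] <- 2                # symmetric pair
  st <- spectral_frame_stats(coch)
  expect_equal(st$centroid, c(1000, 1000))
  expect_lt(st$flatness[1], 1e-3)             # epsilon-limited minimum
  ec <- coch
  ec$energy <- matrix(3, 3, 2)                # equal energy everywhere
  expect_equal(spectral_frame_stats(ec)$flatness, c(1, 1))
})

test_that("spectral variability spans its 0-2 range as constructed", {
  base <- c(1, 2, 3, 4, 5)
  coch <- structure(list(
    energy = cbind(base, base, 2 * mean(base) - base),
    center_frequencies = 1:5 * 100, frame_times = 1:3),
    class = "cochleagram")
  sv <- spectral_variability(coch)
  expect_equal(sv$values, c(0, 2))            # identical, then mirrored
  set.seed(9)
  noisy <- structure(list(
    energy = matrix(rexp(77 * 60), 77, 60),
    center_frequencies = seq_len(77), frame_times = seq_len(60)),
    class = "cochleagram")
  expect_lt(abs(spectral_variability(noisy)$median - 1), 0.25)
  expect_error(spectral_variability(structure(list(
    energy = matrix(1, 2, 1), center_frequencies = 1:2, frame_times = 1),
    class = "cochleagram")), "2 frames")
})

test_that("YIN recovers known fundamentals and flags noise", {
  yt <- yin_track(harmonic_clip(220))
  expect_lt(abs(median(yt$f0) - 220), 1)
  expect_lt(median(yt$aperiodicity), 0.05)

  ys <- yin_track(tone_clip(164.81))
  expect_lt(abs(median(ys$f0) - 164.81), 0.5)

  yn <- yin_track(noise_clip(seed = 3))
  expect_gt(IQR(yn$f0), 20)
  expect_gt(median(yn$aperiodicity), 0.2)

  expect_error(yin_track(tone_clip(440, dur = 0.01)), "shorter")
  expect_error(yin_track(tone_clip(440), fmin_search = 20), "period")
})

test_that("temporal features obey their closed forms", {
  sr <- 44100
  # constant envelope over 250 ms -> centroid at the middle
  const <- tone_clip(1000)
  tf <- temporal_features(const)
  expect_equal(tf$temporal_centroid, 0.125, tolerance = 0.01)

  # linearly increasing envelope on [0, T] -> centroid 2T/3
  t <- seq_len(round(0.25 * sr)) / sr
  ramp <- make_clip((t / max(t)) * sin(2 * pi * 1000 * t), sr,
                    category = "environmental")
  expect_equal(temporal_features(ramp)$temporal_centroid, 2 * 0.25 / 3,
               tolerance = 0.02)

  fast <- standardize_clip(synth_instrument(200, attack_ms = 5,
                                            decay = Inf))
  slow <- standardize_clip(synth_instrument(200, attack_ms = 100,
                                            decay = Inf))
  dlat <- temporal_features(slow)$log_attack_time -
    temporal_features(fast)$log_attack_time
  expect_equal(dlat, log10(100 / 5), tolerance = 0.35)
})

test_that("modulation power spectrum peaks where constructed", {
  # harmonic spacing of 100 Hz -> spectral modulation near 10 cyc/kHz
  mps <- modulation_power_spectrum(harmonic_clip(100, n_harm = 220,
                                                 amp = rep(1, 220)))
  marg <- rowSums(mps$power)
  sel <- mps$spectral_axis > 2
  expect_lt(abs(mps$spectral_axis[sel][which.max(marg[sel])] - 10), 1)
  expect_equal(max(mps$spectral_axis), 31.24, tolerance = 0.02)
  expect_equal(max(mps$temporal_axis), 47.92, tolerance = 0.05)

  # 8 Hz amplitude modulation -> temporal modulation peak at +/- 8 Hz
  sr <- 44100
  t <- seq_len(round(0.25 * sr)) / sr
  set.seed(4)
  am <- make_clip(rnorm(length(t)) * (1 + 0.99 * sin(2 * pi * 8 * t)), sr,
                  category = "environmental")
  mps2 <- modulation_power_spectrum(am)
  tm <- colSums(mps2$power)
  tm[abs(mps2$temporal_axis) < 2] <- 0
  expect_lt(abs(abs(mps2$temporal_axis[which.max(tm)]) - 8), 2.1)

  # stationary noise concentrates at temporal modulation zero
  mps3 <- modulation_power_spectrum(noise_clip(seed = 5))
  expect_equal(mps3$temporal_axis[which.max(colSums(mps3$power))], 0)
  expect_true(all(mps3$spectral_axis >= 0))
  expect_true(all(mps3$power >= 0))
})

test_that("summaries respect ranges, stability and level invariance", {
  ft <- default_features()
  sc <- ft$scalars
  expect_true(all(sc$spectral_flatness_median >= 0 &
                    sc$spectral_flatness_median <= 1))
  expect_true(all(sc$spectral_variability_median >= 0 &
                    sc$spectral_variability_median <= 2))
  expect_true(all(sc$aperiodicity_median >= 0 &
                    sc$aperiodicity_median <= 1))
  iqr_cols <- grep("_iqr$", names(sc), value = TRUE)
  for (cl in iqr_cols) expect_true(all(sc[[cl]] >= 0))

  # stable pitch for vocal clips
  expect_true(all(sc$f0_iqr[sc$category == "vocal"] < 5))
  # every environmental clip is more aperiodic than every vocal clip
  expect_gt(min(sc$aperiodicity_median[sc$category == "environmental"]),
            max(sc$aperiodicity_median[sc$category == "vocal"]))

  clip <- default_set()$clips[["bassoon"]]
  row1 <- summarize_clip(clip)
  clip2 <- clip
  clip2$samples <- clip2$samples * 0.5  # gain change, rescaled in-range
  row2 <- summarize_clip(clip2)
  for (nm in c("spectral_centroid_median", "spectral_flatness_median",
               "spectral_variability_median", "aperiodicity_median",
               "f0_median")) {
    expect_equal(row1[[nm]], row2[[nm]], tolerance = 1e-6)
  }
  expect_error(summarize_clip(audio_clip(numeric(100) + 0, 44100,
                                         category = "environmental")),
               "silent")
})
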