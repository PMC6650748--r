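test_that("default set has the prescribed composition", {
  set <- default_set()
  cats <- vapply(set$clips, `[[`, "", "category")
  expect_length(set$clips, 36L)
  expect_equal(unname(table(cats)[c("vocal", "instrument",
                                    "environmental")]),
               rep(12L, 3), ignore_attr = TRUE)
  expect_length(set$renderings, 12L)
  expect_true(all(lengths(set$renderings) == 10L))
  expect_true(set$default_note %in% names(set$renderings[[1]]))
})

test_that("vocal matched notes stay within the nine-note set", {
  set <- default_set()
  printed <- c("A2", "Ab2", "Ab3", "B2", "B3", "Bb2", "Bb3", "C3", "G2")
  expect_true(all(set$note_table %in% printed))
  expect_length(set$note_table, 12L)
})

test_that("synthesis is reproducible and rejects bad configs", {
  s1 <- build_stimulus_set(seed = 7)
  s2 <- build_stimulus_set(seed = 7)
  expect_identical(s1$clips[["m1_a"]]$samples, s2$clips[["m1_a"]]$samples)
  expect_identical(s1$clips[["impact_2"]]$samples,
                   s2$clips[["impact_2"]]$samples)
  s3 <- build_stimulus_set(seed = 8)
  expect_false(identical(s1$clips[["m1_a"]]$samples,
                         s3$clips[["m1_a"]]$samples))
  expect_error(build_stimulus_set(config = list()), "config")
  cfg <- default_stimulus_config()
  cfg$instruments <- cfg$instruments[1:5, ]
  expect_error(build_stimulus_set(config = cfg), "12 instruments")
})

test_that("vowel synthesis hits the requested F0 and formant contrast", {
  v <- standardize_clip(synth_vowel(220, "a", seed = 3))
  yt <- yin_track(v)
  expect_lt(abs(median(yt$f0) - 220), 1)
  # /i/ concentrates more energy near its high second formant than /a/
  va <- standardize_clip(synth_vowel(110, "a", seed = 3))
  vi <- standardize_clip(synth_vowel(110, "i", seed = 3))
  hi_band <- function(clip) {
    coch <- erb_cochleagram(clip)
    sel <- coch$center_frequencies > 1800 & coch$center_frequencies < 2800
    sum(coch$energy[sel, ]) / sum(coch$energy)
  }
  expect_gt(hi_band(vi), hi_band(va))
  expect_error(synth_vowel(30, "a"), "60-400")
})

test_that("instrument attack and brightness behave monotonically", {
  fast <- standardize_clip(synth_instrument(164.81, attack_ms = 5))
  slow <- standardize_clip(synth_instrument(164.81, attack_ms = 100))
  expect_lt(temporal_features(fast)$log_attack_time,
            temporal_features(slow)$log_attack_time)
  dull <- standardize_clip(synth_instrument(164.81, brightness = 1))
  bright <- standardize_clip(synth_instrument(164.81, brightness = 8))
  cent <- function(clip) {
    median(spectral_frame_stats(erb_cochleagram(clip))$centroid,
           na.rm = TRUE)
  }
  expect_gt(cent(bright), cent(dull))
  yt <- yin_track(standardize_clip(synth_instrument(164.81)))
  expect_lt(abs(median(yt$f0) - 164.81), 1)
  expect_error(synth_instrument(164.81, attack_ms = 400, duration = 0.3),
               "attack")
})

test_that("environmental recipes are noise-dominated with medium contrasts", {
  imp <- standardize_clip(synth_environmental("impact", seed = 2))
  air <- standardize_clip(synth_environmental("air", seed = 2))
  expect_lt(temporal_features(imp)$temporal_centroid,
            temporal_features(air)$temporal_centroid)
  flat <- function(clip) {
    median(spectral_frame_stats(erb_cochleagram(clip))$flatness,
           na.rm = TRUE)
  }
  vow <- standardize_clip(synth_vowel(150, "a", seed = 2))
  for (m in c("air", "liquid", "deformation", "impact", "mechanical",
              "movement")) {
    env <- standardize_clip(synth_environmental(m, seed = 4))
    expect_gt(flat(env), flat(vow))
    yt <- yin_track(env)
    expect_gt(IQR(yt$f0), 5)  # erratic pitch track, vs < 1 Hz periodic
  }
})

test_that("category-level aperiodicity ordering holds on seeded sets", {
  for (seed in c(1, 2)) {
    set <- if (seed == 1) default_set() else
      standardize_set(build_stimulus_set(seed = seed))
    ap <- function(lab) median(yin_track(set$clips[[lab]])$aperiodicity)
    labs <- names(set$clips)
    cats <- vapply(set$clips, `[[`, "", "category")
    env <- mean(vapply(labs[cats == "environmental"], ap, 0))
    per <- mean(vapply(labs[cats != "environmental"], ap, 0))
    expect_gt(env, per)
  }
})

test_that("all clips standardize to exactly 250 ms without error", {
  set <- default_set()
  lens <- vapply(set$clips, length, 0L)
  expect_true(all(lens == 11025L))
  rms <- vapply(set$clips, function(cl) sqrt(mean(cl$samples^2)), 0)
  expect_equal(rms, rep(0.05, 36), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("WAV round-trip preserves samples", {
  clip <- tone_clip(440, dur = 0.05)
  f <- tempfile(fileext = ".wav")
  write_wav(clip, f, format = "float32")
  back <- read_wav(f)
  expect_equal(back$samples, clip$samples, tolerance = 1e-7)
  expect_equal(back$sample_rate, 44100)
  write_wav(clip, f, format = "pcm16")
  back16 <- read_wav(f)
  expect_equal(back16$samples, clip$samples, tolerance = 1e-4)
  unlink(f)
})
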