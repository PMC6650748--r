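#!/usr/bin/env Rscript
# Stage 1: synthesize the 36-item stimulus set (12 vowel utterances from 6
# simulated speakers, 12 instrument tones rendered at 10 pairing notes, 12
# environmental tokens over 6 excitation media) and standardize every clip
# to 250 ms from onset with 5-ms ramps and a common RMS level.
#
# Outputs: results/manifest.csv (+ optional WAV files with --wav)

suppressPackageStartupMessages(library(audissim))
seed <- as.integer(Sys.getenv("AUDISSIM_SEED", "1"))
dir.create("results", showWarnings = FALSE)

message("synthesizing stimulus set (seed ", seed, ") ...")
set <- build_stimulus_set(seed = seed)
set <- standardize_set(set)

manifest <- stimulus_manifest(set)
write.csv(manifest, "results/manifest.csv", row.names = FALSE)
saveRDS(set, "results/stimulus_set.rds")

if ("--wav" %in% commandArgs(trailingOnly = TRUE)) {
  dir.create("results/wav", showWarnings = FALSE)
  for (cl in set$clips) {
    write_wav(cl, file.path("results/wav", paste0(cl$label, ".wav")))
  }
  message("wrote ", length(set$clips), " WAV files under results/wav/")
}

message("clips per category:")
print(table(manifest$category))
message("vocal utterances and their matched notes:")
print(manifest[manifest$category == "vocal", c("label", "note", "f0")])
message("all clips are ", length(set$clips[[1]]$samples),
        " samples (250 ms at 44.1 kHz); manifest in results/manifest.csv")
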