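#!/usr/bin/env Rscript
# Stage 3: simulate the two behavioral experiments against the synthetic
# stimuli. Dissimilarity raters respond 1-9 to each of their 630
# counterbalanced ordered pairs (two complementary lists, 3 blocks of 210)
# as a noisy monotone function of weighted acoustic distances;
# identifiers label each of the 36 items once per block with confusions
# concentrated among acoustically close items.
#
# Inputs:  results/feature_table.rds
# Outputs: results/ratings.csv, results/id_trials.csv,
#          results/reliability.txt

suppressPackageStartupMessages(library(audissim))
seed <- as.integer(Sys.getenv("AUDISSIM_SEED", "1"))
features <- readRDS("results/feature_table.rds")

lists <- counterbalance_lists(features$items)
stopifnot(nrow(lists[[1]]) == 630L, nrow(lists[[2]]) == 630L)

message("simulating 50 dissimilarity raters ...")
ratings <- simulate_ratings(features, rater_model(),
                            n_participants = 50, lists = lists,
                            seed = seed + 51L)
write.csv(ratings, "results/ratings.csv", row.names = FALSE)

rel <- split_half_reliability(ratings, n_splits = 100,
                              seed = seed + 91L)$reliability
writeLines(sprintf("split_half_reliability %.4f", rel),
           "results/reliability.txt")
message(sprintf("split-half reliability (Spearman-Brown adjusted): %.3f",
                rel))
message(sprintf("rating use of scale: %.1f%% ones, %.1f%% nines",
                100 * mean(ratings$rating == 1),
                100 * mean(ratings$rating == 9)))

message("simulating 21 identifiers over 10 blocks ...")
trials <- simulate_identification(features, identifier_model(),
                                  n_participants = 21, n_blocks = 10,
                                  seed = seed + 81L)
write.csv(trials, "results/id_trials.csv", row.names = FALSE)
message(sprintf("mean item accuracy %.3f (chance 1/36 = %.3f)",
                mean(trials$stimulus == trials$response), 1 / 36))
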