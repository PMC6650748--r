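#!/usr/bin/env Rscript
# Stage 4: representational similarity analysis. The group-averaged
# dissimilarity matrix is correlated (standard and semi-partial Kendall
# tau) with the item-pair distance matrix of each acoustic feature, over
# all 630 unordered pairs and over the six within/between-category
# subsets, with one-sided permutation p-values (10,000 iterations,
# p = (r+1)/(n+1)) and Benjamini-Hochberg correction within each
# subset-by-statistic family. F0 features enter only the vocal-vocal
# (median + IQR) and vocal-instrument (IQR) subsets, where F0 was free to
# vary.
#
# Inputs:  results/feature_table.rds, results/ratings.csv
# Outputs: results/rsa_report.csv

suppressPackageStartupMessages(library(audissim))
seed <- as.integer(Sys.getenv("AUDISSIM_SEED", "1"))
features <- readRDS("results/feature_table.rds")
ratings <- read.csv("results/ratings.csv")

behavior <- aggregate_ratings(ratings, features$items)

message("running RSA (7 subsets, 10,000 permutations per test) ...")
report <- rsa_report(behavior, features, n = 10000, seed = seed + 61L)
write.csv(report, "results/rsa_report.csv", row.names = FALSE)

ov <- report[report$subset == "overall", ]
for (st in c("tau", "semi_partial")) {
  top <- ov[ov$statistic == st, ]
  top <- top[order(-top$tau), ][1:5, ]
  message("top overall features (", st, "):")
  print(top[, c("feature", "tau", "p", "p_fdr")], row.names = FALSE,
        digits = 3)
}
sig <- aggregate(p_fdr ~ subset + statistic, report,
                 function(p) sum(p < 0.05))
names(sig)[3] <- "n_significant"
message("significant features (FDR < .05) per subset and statistic:")
print(sig, row.names = FALSE)
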