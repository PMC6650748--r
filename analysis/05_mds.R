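#!/usr/bin/env Rscript
# Stage 5: ordinal multidimensional scaling of the group-averaged
# dissimilarity matrix (diagonal fixed at the scale minimum of 1), by
# SMACOF stress majorization with primary-tie monotone regression. A
# scree over 1-6 dimensions motivates the 3-D solution, whose axes are
# then correlated (Kendall tau, FDR within dimension) with the scalar
# acoustic features.
#
# Inputs:  results/feature_table.rds, results/ratings.csv
# Outputs: results/mds_scree.csv, results/mds_coordinates.csv,
#          results/mds_dimension_correlations.csv

suppressPackageStartupMessages(library(audissim))
seed <- as.integer(Sys.getenv("AUDISSIM_SEED", "1"))
features <- readRDS("results/feature_table.rds")
ratings <- read.csv("results/ratings.csv")
behavior <- aggregate_ratings(ratings, features$items)

message("stress by dimensionality ...")
scree <- stress_scree(behavior, max_dimensions = 6, n_starts = 8,
                      seed = seed + 71L)
write.csv(scree, "results/mds_scree.csv", row.names = FALSE)
print(scree, digits = 3, row.names = FALSE)

sol <- ordinal_mds(behavior, n_dimensions = 3, n_starts = 8,
                   seed = seed + 71L)
message(sprintf("3-D solution stress-1 = %.4f (majorization monotone: %s)",
                sol$stress,
                all(diff(sol$stress_sequence) <= 1e-8)))

dfc <- dimension_feature_correlations(sol, features)
write.csv(data.frame(item = rownames(dfc$solution$coordinates),
                     category = features$categories,
                     dfc$solution$coordinates),
          "results/mds_coordinates.csv", row.names = FALSE)
write.csv(dfc$table, "results/mds_dimension_correlations.csv",
          row.names = FALSE)

for (k in 1:3) {
  dk <- dfc$table[dfc$table$dimension == k, ]
  dk <- dk[order(-abs(dk$tau)), ][1:3, ]
  message("dimension ", k, " correlates with:")
  print(dk[, c("feature", "tau", "p_fdr")], row.names = FALSE,
        digits = 2)
}
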