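# End-to-end orchestration of the synthetic study: synthesis ->
# preprocessing -> features -> simulated behavior -> dissimilarity
# matrices -> RSA + MDS + identification analyses, with all tables written
# as CSV under an output directory.

#' Pipeline run configuration
#'
#' @param seed Master integer seed; every stochastic stage derives its
#'   seed from it.
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @param n_participants_rating,n_participants_id Simulated sample sizes.
#' @param n_permutations Permutations per RSA test.
#' @param mds_dimensions,mds_starts Ordinal MDS settings.
#' @param stages Character vector of stages to run after the shared
#'   synthesis/feature steps: any of `"rsa"`, `"mds"`, `"behavior"`.
#' @param rater,identifier Model objects ([rater_model()],
#'   [identifier_model()]).
#' @param pair_mode Passed to [rsa_report()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = NULL,
                       n_participants_rating = 50,
                       n_participants_id = 21,
                       n_permutations = 10000,
                       mds_dimensions = 3, mds_starts = 8,
                       stages = c("rsa", "mds", "behavior"),
                       rater = rater_model(),
                       identifier = identifier_model(),
                       pair_mode = "unordered") {
  structure(list(seed = seed, out_dir = out_dir,
                 n_participants_rating = n_participants_rating,
                 n_participants_id = n_participants_id,
                 n_permutations = n_permutations,
                 mds_dimensions = mds_dimensions,
                 mds_starts = mds_starts, stages = stages,
                 rater = rater, identifier = identifier,
                 pair_mode = pair_mode),
            class = "run_config")
}

.write_csv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full synthetic study
#'
#' Executes the stages enabled in the configuration and returns (and
#' optionally writes) all intermediate and final tables. Identical
#' configurations produce identical outputs.
#'
#' @param config A [run_config()].
#' @param features Optionally, a precomputed [feature_table()] (skips
#'   synthesis and feature extraction).
#' @param quiet Suppress per-stage messages.
#' @return A list with (depending on stages) `set`, `features`, `ratings`,
#'   `behavior_matrix`, `rsa`, `mds`, `dimension_correlations`,
#'   `id_trials`, `accuracy`, `accuracy_tests`, `reliability`,
#'   `confusion_tau`.
#' @export
run_pipeline <- function(config = run_config(), features = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  out <- list(config = config)
  if (!is.null(config$out_dir) &&
      !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }

  if (is.null(features)) {
    say("synthesizing and standardizing stimulus set (seed %d)",
        config$seed)
    set <- standardize_set(build_stimulus_set(seed = config$seed))
    out$set <- set
    .write_csv(stimulus_manifest(set), config$out_dir, "manifest.csv")
    say("extracting acoustic features")
    features <- feature_table(set)
  }
  out$features <- features
  .write_csv(features$scalars, config$out_dir, "features_scalar.csv")

  say("simulating dissimilarity ratings (%d participants)",
      config$n_participants_rating)
  lists <- counterbalance_lists(features$items)
  ratings <- simulate_ratings(features, config$rater,
                              config$n_participants_rating, lists,
                              seed = config$seed + 1000L)
  out$ratings <- ratings
  .write_csv(ratings, config$out_dir, "ratings.csv")
  behavior <- aggregate_ratings(ratings, features$items)
  out$behavior_matrix <- behavior

  if ("rsa" %in% config$stages) {
    say("RSA (%d permutations per test)", config$n_permutations)
    out$rsa <- rsa_report(behavior, features, n = config$n_permutations,
                          seed = config$seed + 2000L,
                          pair_mode = config$pair_mode)
    .write_csv(out$rsa, config$out_dir, "rsa_report.csv")
  }

  if ("mds" %in% config$stages) {
    say("ordinal MDS (%d dimensions, %d starts)", config$mds_dimensions,
        config$mds_starts)
    sol <- ordinal_mds(behavior, n_dimensions = config$mds_dimensions,
                       n_starts = config$mds_starts,
                       seed = config$seed + 3000L)
    dfc <- dimension_feature_correlations(sol, features)
    out$mds <- dfc$solution
    out$dimension_correlations <- dfc$table
    .write_csv(data.frame(item = rownames(dfc$solution$coordinates),
                          dfc$solution$coordinates),
               config$out_dir, "mds_coordinates.csv")
    .write_csv(dfc$table, config$out_dir, "mds_dimension_correlations.csv")
  }

  if ("behavior" %in% config$stages) {
    say("simulating identification (%d participants) and reliability",
        config$n_participants_id)
    trials <- simulate_identification(features, config$identifier,
                                      config$n_participants_id,
                                      seed = config$seed + 4000L)
    out$id_trials <- trials
    acc <- item_accuracy(trials, features$items)
    out$accuracy <- acc
    out$accuracy_tests <- accuracy_vs_chance(acc, 1 / length(features$items))
    .write_csv(out$accuracy_tests, config$out_dir, "accuracy_tests.csv")
    sub_map <- stats::setNames(features$subcategories, features$items)
    out$accuracy_subcategory <- recode_subcategory(trials, features$items,
                                                   sub_map)
    conf <- confusion_counts(trials, features$items)
    out$confusion <- conf
    out$confusion_tau <- confusion_dissim_correlation(conf, behavior)
    out$reliability <- split_half_reliability(
      ratings, seed = config$seed + 5000L)$reliability
  }
  say("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  out
}
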