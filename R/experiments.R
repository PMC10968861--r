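# Reproduction experiments: end-to-end runs over the synthetic cohort that
# mirror the pipeline's main analyses (delta vs single-time-point feature
# sets for progression prediction).

#' Delta-vs-baseline signal-recovery experiment
#'
#' For each of `n_seeds` replicate cohorts: simulate a two-time-point
#' image cohort whose progression depends on the relative TLG change plus
#' a heterogeneity-change term, extract the full feature set at both time
#' points, assemble the requested feature-set combinations, and estimate
#' nested-CV classification accuracy for each. Returns the per-seed
#' accuracy matrix, from which the delta-beats-baseline ordering can be
#' tested (paired sign test over seeds).
#'
#' @param n_seeds number of replicate cohorts.
#' @param n_subjects subjects per cohort.
#' @param combos feature-set combinations to compare.
#' @param model classifier for the nested CV.
#' @param cfg a [cv_config()]; its seed is re-derived per replicate.
#' @param spec_args overrides for [cohort_spec()] besides `n_subjects` and
#'   `seed`.
#' @param rim_k shells kept per indexing direction during extraction.
#' @param seed master seed.
#' @return data.frame with one row per seed x combo: `seed`, `combo`,
#'   `accuracy`, `f1`, `roc_auc`.
#' @export
delta_vs_baseline_experiment <- function(n_seeds = 10L, n_subjects = 100L,
                                         combos = c("baseline", "rel_delta",
                                                    "baseline+rel_delta"),
                                         model = "lda",
                                         cfg = cv_config(outer_folds = 5L,
                                                         outer_repeats = 2L,
                                                         inner_folds = 3L,
                                                         inner_repeats = 1L,
                                                         holdout_fraction = 0,
                                                         max_features = 3L),
                                         spec_args = list(), rim_k = 4L,
                                         seed = 1L) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    args <- utils::modifyList(list(
      n_subjects = n_subjects,
      grid_shape = c(28L, 28L, 28L), spacing = c(5, 5, 5),
      radius_range_mm = c(15, 28),
      seed = derive_seed(seed, paste0("cohort", s))), spec_args)
    co <- simulate_cohort(do.call(cohort_spec, args))
    tabs <- list(
      baseline = extract_feature_table(lapply(co$scans, `[[`, "baseline"),
                                       rim_k = rim_k),
      eot = extract_feature_table(lapply(co$scans, `[[`, "eot"),
                                  rim_k = rim_k))
    y <- co$outcomes$progression
    for (cb in combos) {
      # a degenerate relative delta (e.g. Dmax 0 at baseline for every
      # single-lesion subject) yields an all-missing column that is dropped
      fs <- suppressWarnings(mean_impute(build_feature_set(tabs, cb)))
      stopifnot(identical(fs$subject_id, co$outcomes$subject_id))
      X <- as.matrix(fs[, feature_columns(fs), drop = FALSE])
      cfg_s <- cfg
      cfg_s$seed <- derive_seed(seed, paste0("cv", s, cb))
      rep <- suppressWarnings(nested_cv_classify(X, y, model, cfg_s))
      sm <- rep$summary
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, combo = cb,
        accuracy = sm$mean[sm$metric == "accuracy"],
        f1 = sm$mean[sm$metric == "f1"],
        roc_auc = sm$mean[sm$metric == "roc_auc"],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Paired sign test that one combo beats another across seeds
#'
#' @param results output of [delta_vs_baseline_experiment()].
#' @param better,worse combo names to compare.
#' @return list with `wins`, `losses`, `p_value` (one-sided binomial).
#' @export
combo_sign_test <- function(results, better, worse) {
  a <- results$accuracy[results$combo == better]
  b <- results$accuracy[results$combo == worse]
  wins <- sum(a > b); losses <- sum(a < b)
  p <- if (wins + losses == 0) 1 else
    stats::binom.test(wins, wins + losses, alternative = "greater")$p.value
  list(wins = wins, losses = losses, p_value = p)
}
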