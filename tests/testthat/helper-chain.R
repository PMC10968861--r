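# end-to-end chain through the CLI verbs on a small synthetic cohort
# (shared by the CLI smoke test and the reproducibility check)
run_chain <- function(dir, seed, n_subjects = 14) {
  cfg <- list(
    seed = seed,
    simulate = list(n_subjects = n_subjects, beta0 = 2,
                    grid_shape = c(20L, 20L, 20L), spacing = c(5, 5, 5),
                    radius_range_mm = c(12, 22),
                    out_dir = file.path(dir, "cohort")),
    extract = list(manifest = file.path(dir, "cohort", "manifest.csv"),
                   out_dir = file.path(dir, "cohort"), rim_k = 4L),
    delta = list(baseline = file.path(dir, "cohort",
                                      "features_baseline.csv"),
                 eot = file.path(dir, "cohort", "features_eot.csv"),
                 out_dir = file.path(dir, "cohort")),
    classify = list(baseline = file.path(dir, "cohort",
                                         "features_baseline.csv"),
                    eot = file.path(dir, "cohort", "features_eot.csv"),
                    outcomes = file.path(dir, "cohort", "outcomes.csv"),
                    combo = "rel_delta", model = "lda",
                    cv = list(outer_folds = 3L, outer_repeats = 1L,
                              inner_folds = 2L, inner_repeats = 1L,
                              holdout_fraction = 0, max_features = 2L),
                    out_dir = dir),
    ttp = list(baseline = file.path(dir, "cohort", "features_baseline.csv"),
               eot = file.path(dir, "cohort", "features_eot.csv"),
               outcomes = file.path(dir, "cohort", "outcomes.csv"),
               combo = "rel_delta", methods = "lasso", cv_folds = 3L,
               out_dir = dir))
  cfile <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfile)
  for (verb in c("simulate", "extract", "delta", "classify", "ttp")) {
    suppressWarnings(cli_run(c(verb, cfile), verbose = FALSE))
  }
  invisible(cfile)
}

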