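# Shared small synthetic cohort, generated once per test run.
small_cohort_cache <- new.env(parent = emptyenv())

small_cohort_features <- function() {
  if (is.null(small_cohort_cache$features)) {
    co <- generate_cohort(cohort_config(n_per_class = 5, seed = 42))
    small_cohort_cache$catalog <- build_superset_catalog()
    small_cohort_cache$cohort <- co
    small_cohort_cache$features <-
      extract_cohort_features(co, small_cohort_cache$catalog)
  }
  small_cohort_cache$features
}

small_cohort <- function() {
  invisible(small_cohort_features())
  small_cohort_cache$cohort
}

default_catalog <- function() {
  if (is.null(small_cohort_cache$catalog)) {
    small_cohort_cache$catalog <- build_superset_catalog()
  }
  small_cohort_cache$catalog
}

# Reduced classifier grids used for the stochastic calibration runs.
reduced_grids <- function() {
  default_model_grids(knn_k = c(3, 5), logistic_C = c(0.05, 0.1),
                      svm_C = c(0.01, 0.05))
}

# One end-to-end run on a single maneuver: simulate, extract, rank + BB
# selection inside every outer fold, nested LOO; returns the evaluation.
single_maneuver_run <- function(seed, effect, n_per_class = 8,
                                maneuver = "max_contraction",
                                selection = "bb",
                                noise_sd_kpa = 0.8) {
  cfg <- cohort_config(n_per_class = n_per_class, seed = seed,
                       noise_sd_kpa = noise_sd_kpa, effect = effect)
  cohort <- generate_cohort(cfg)
  cohort <- cohort[cohort$maneuver == maneuver, ]
  tbl <- extract_cohort_features(cohort, default_catalog())[[maneuver]]
  nested_loo_evaluate(
    tbl, reduced_grids(), selection = selection,
    selection_scope = "outer_fold",
    cfg = selection_config(n_keep = 8, ranking_method = "pearson",
                           seed = seed),
    subset_dim = 3
  )
}
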