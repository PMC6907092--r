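lab <- function(x) ifelse(x == 1, "incontinent", "continent")

test_that("classification metrics match confusion-matrix enumeration", {
  truth48 <- lab(rep(c(0, 1), 24))
  expect_equal(
    classification_metrics(truth48, truth48),
    tibble::tibble(accuracy = 1, precision = 1, recall = 1)
  )
  pred <- truth48
  flip <- c(1:6, 25:29)  # 11 errors leave 37 of 48 correct
  pred[flip] <- lab(1 - (truth48[flip] == "incontinent"))
  expect_equal(classification_metrics(pred, truth48)$accuracy, 37 / 48)

  # TP = 3, FP = 1, FN = 2, TN = 2
  truth <- lab(c(1, 1, 1, 1, 1, 0, 0, 0))
  pred <- lab(c(1, 1, 1, 0, 0, 1, 0, 0))
  m <- classification_metrics(pred, truth)
  expect_equal(m$accuracy, 5 / 8)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 5)

  expect_warning(
    z <- classification_metrics(lab(c(0, 0)), lab(c(0, 1))),
    "Zero denominator"
  )
  expect_equal(z$precision, 0)
  expect_error(classification_metrics(c("yes", "no"), truth[1:2]), "Labels")
  expect_error(classification_metrics(pred, truth[1:3]), "equal length")
})

test_that("McNemar comparison matches closed-form chi-square tails", {
  truth <- lab(rep(0, 10))
  a <- truth
  expect_equal(mcnemar_compare(a, a, truth)$p_value, 1)
  expect_equal(mcnemar_compare(a, a, truth)$statistic, 0)

  # b = 5, c = 5: statistic (|0| - 1)^2 / 10 = 0.1
  a <- truth; a[1:5] <- lab(1)
  b <- truth; b[6:10] <- lab(1)
  r <- mcnemar_compare(a, b, truth)
  expect_equal(r$b, 5)
  expect_equal(r$c, 5)
  expect_equal(r$statistic, 0.1)
  expect_equal(r$p_value, 0.752, tolerance = 1e-3)

  # b = 10, c = 0: statistic 81/10 = 8.1
  b_all_wrong <- lab(rep(1, 10))
  r2 <- mcnemar_compare(truth, b_all_wrong, truth)
  expect_equal(r2$statistic, 8.1)
  expect_lt(r2$p_value, 0.01)

  ex <- mcnemar_compare(a, b, truth, exact = TRUE)
  expect_equal(ex$p_value, stats::binom.test(5, 10, 0.5)$p.value)
})

separable_table <- function(n_per_class = 5, gap = 8, seed = 2) {
  set.seed(seed)
  n <- 2 * n_per_class
  tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    label = rep(c("continent", "incontinent"), each = n_per_class),
    f1 = c(stats::runif(n_per_class), stats::runif(n_per_class) + gap),
    f2 = stats::rnorm(n, sd = 0.5)
  )
}

test_that("inner LOO selects the lone candidate and perfect configurations", {
  tbl <- separable_table()
  one <- inner_loo_select(tbl, default_model_grids(knn_k = 3,
                                                   logistic_C = NULL,
                                                   svm_C = NULL))
  expect_equal(one$overall$model, "knn")
  expect_equal(one$overall$param, 3)

  sel <- inner_loo_select(tbl, reduced_grids())
  expect_equal(sel$overall$accuracy, 1)
  expect_equal(nrow(sel$per_model), 3)
})

test_that("configuration ties break toward the simpler model", {
  tbl <- separable_table()
  sel <- inner_loo_select(tbl, default_model_grids(knn_k = c(1, 3, 5),
                                                   logistic_C = NULL,
                                                   svm_C = NULL))
  # all k are perfect on separable data; the largest k wins the tie
  expect_equal(sel$overall$param, 5)
  sel2 <- inner_loo_select(tbl, default_model_grids(knn_k = NULL,
                                                    logistic_C = NULL,
                                                    svm_C = c(0.01, 0.05)))
  expect_equal(sel2$overall$param, 0.01)
})

test_that("nested LOO covers each subject once and tallies selections", {
  tbl <- separable_table(n_per_class = 5)
  rep_ <- nested_loo_evaluate(tbl, reduced_grids())
  expect_equal(sort(rep_$outer_predictions$subject_id), sort(tbl$subject_id))
  expect_equal(sum(rep_$selection_frequency$count), nrow(tbl))
  expect_true(all(rep_$metrics$accuracy >= 0 & rep_$metrics$accuracy <= 1))
  expect_equal(rep_$metrics$accuracy[rep_$metrics$model == "best"], 1)
  # fold-best accuracy is reproducible from the stored per-fold predictions
  expect_equal(
    mean(rep_$outer_predictions$pred_best == rep_$outer_predictions$truth),
    rep_$metrics$accuracy[rep_$metrics$model == "best"]
  )
  expect_error(nested_loo_evaluate(tbl[1:3, ], reduced_grids()), "at least 4")
})

test_that("outer-fold selection is recomputed without the held-out subject", {
  tbl <- random_feature_table(n_per_class = 5, p = 12,
                              shift = c(3, 3, 3, rep(0, 9)), seed = 13)
  cfg <- selection_config(n_keep = 8, ranking_method = "pearson", seed = 1)
  rep_ <- nested_loo_evaluate(tbl, reduced_grids(), selection = "bb",
                              selection_scope = "outer_fold", cfg = cfg,
                              subset_dim = 3)
  for (i in c(1, 4)) {
    manual <- branch_and_bound_select(rank_filter(tbl[-i, ], cfg), 3, cfg)
    expect_setequal(rep_$outer_predictions$selected_features[[i]],
                    manual$selected)
  }
  ff <- feature_selection_frequency(rep_)
  expect_equal(sum(ff$count), nrow(tbl) * 3)
  expect_true(all(ff$out_of == nrow(tbl)))
})

test_that("global-scope selection fixes one subset for every fold", {
  tbl <- random_feature_table(n_per_class = 5, p = 12,
                              shift = c(3, 3, 3, rep(0, 9)), seed = 14)
  cfg <- selection_config(n_keep = 8, ranking_method = "pearson", seed = 1)
  rep_ <- nested_loo_evaluate(tbl, reduced_grids(), selection = "bb",
                              selection_scope = "global", cfg = cfg,
                              subset_dim = 3)
  expect_length(unique(rep_$outer_predictions$selected_features), 1)
  expect_length(rep_$global_subset$selected, 3)
})

test_that("the combined scheme concatenates four tagged per-maneuver subsets", {
  tables <- lapply(c("endurance", "valsalva", "max_contraction", "wave"),
                   function(m) {
    tbl <- random_feature_table(n_per_class = 6, p = 10,
                                shift = c(2, 2, rep(0, 8)),
                                seed = match(m, c("endurance", "valsalva",
                                                  "max_contraction", "wave")))
    names(tbl)[-(1:2)] <- paste(m, names(tbl)[-(1:2)], sep = ".")
    tbl
  })
  cfg <- selection_config(n_keep = 10, seed = 1)
  ct <- combined_subset_table(tables, cfg, dim = 3)
  expect_length(feature_names(ct$table), 4 * 3)
  expect_false(any(duplicated(feature_names(ct$table))))
  expect_equal(ct$table$subject_id, tables[[1]]$subject_id)

  bad <- tables
  bad[[2]] <- bad[[2]][c(2, 1, 3:12), ]
  expect_error(combined_subset_table(bad, cfg, dim = 3), "share subject")

  res <- combined_scheme(tables, reduced_grids(), selection = "none",
                         cfg = cfg, dim = 3)
  expect_s3_class(res$report, "pf_evaluation")
  expect_equal(glance(res)$n_features, 12)
  expect_equal(nrow(tidy(res)), 12)
})

test_that("top-feature report handles ties, disjoint supports and length", {
  tbl <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10),
    label = rep(c("continent", "incontinent"), each = 5),
    same = rep(c(1, 2, 3, 4, 5), 2),
    disjoint = c(1:5, 6:10)
  )
  rep_ <- suppressWarnings(top_feature_report(tbl, c("same", "disjoint")))
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$mannwhitney_p[rep_$feature == "same"], 1)
  expect_equal(rep_$mannwhitney_p[rep_$feature == "disjoint"],
               2 / choose(10, 5))
  expect_equal(rep_$median_continent[rep_$feature == "disjoint"], 3)
  expect_equal(rep_$median_incontinent[rep_$feature == "disjoint"], 8)
  expect_error(top_feature_report(tbl, "nope"), "Unknown feature")
})

test_that("PCA projection captures perfect correlation and planar geometry", {
  tbl <- tibble::tibble(
    subject_id = sprintf("S%d", 1:6),
    label = rep(c("continent", "incontinent"), each = 3),
    f1 = c(1, 2, 3, 4, 5, 6),
    f2 = 2 * c(1, 2, 3, 4, 5, 6) + 1
  )
  pc <- pca_projection(tbl)
  expect_equal(attr(pc, "explained")[1], 1)
  expect_equal(nrow(pc), 6)

  # three points always span a plane: the 2-component scores preserve the
  # pairwise distances of the standardized features exactly
  set.seed(5)
  tri <- tibble::tibble(
    subject_id = c("A", "B", "C"),
    label = c("continent", "continent", "incontinent"),
    f1 = stats::rnorm(3), f2 = stats::rnorm(3), f3 = stats::rnorm(3)
  )
  pc3 <- pca_projection(tri)
  d_scores <- stats::dist(cbind(pc3$PC1, pc3$PC2))
  d_orig <- stats::dist(scale(as.matrix(tri[c("f1", "f2", "f3")])))
  expect_equal(as.numeric(d_scores), as.numeric(d_orig), tolerance = 1e-9)

  expect_warning(
    pca_projection(dplyr::mutate(tbl, f3 = 1)),
    "zero-variance"
  )
})

test_that("pairwise model tests cover the three classifier pairs", {
  tbl <- separable_table(n_per_class = 4)
  rep_ <- nested_loo_evaluate(tbl, reduced_grids())
  pt <- pairwise_model_tests(rep_)
  expect_equal(nrow(pt), 3)
  expect_true(all(pt$p_value >= 0 & pt$p_value <= 1))
})
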