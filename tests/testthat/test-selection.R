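test_that("Pearson scores match the correlation formula and its edge cases", {
  tbl <- tibble::tibble(
    subject_id = sprintf("S%d", 1:6),
    label = rep(c("continent", "incontinent"), each = 3),
    exact = c(0, 0, 0, 1, 1, 1),
    const = rep(2.5, 6),
    mixed = c(1.2, 0.7, 1.9, 2.1, 3.3, 2.8)
  )
  s <- pearson_scores(tbl)
  expect_equal(s$score[s$feature == "exact"], 1)
  expect_equal(s$score[s$feature == "const"], 0)
  # direct transcription of the sample correlation formula
  x <- tbl$mixed
  y <- c(0, 0, 0, 1, 1, 1)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(s$score[s$feature == "mixed"], abs(r))
})

test_that("RELIEF separates an informative feature and zeroes a constant one", {
  tbl <- tibble::tibble(
    subject_id = sprintf("S%d", 1:4),
    label = rep(c("continent", "incontinent"), each = 2),
    a = c(0, 0.1, 0.9, 1),
    b = rep(3, 4)
  )
  w <- relief_scores(tbl)
  # hand pass on min-max scaled a = (0, .1, .9, 1): nearest hits are the
  # class partners (diff 0.1 each), nearest misses sit across the gap with
  # diffs 0.9, 0.8, 0.8, 0.9 for the four subjects in turn
  expect_gt(w$weight[w$feature == "a"], 0)
  expect_equal(w$weight[w$feature == "a"],
               mean(c(0.9, 0.8, 0.8, 0.9) - 0.1))
  expect_equal(w$weight[w$feature == "b"], 0)
})

test_that("RELIEF weights are stable under whole-table duplication", {
  tbl <- random_feature_table(n_per_class = 4, p = 5, shift = c(2, 0), seed = 5)
  twice <- dplyr::bind_rows(tbl, tbl)
  twice$subject_id <- sprintf("S%02d", seq_len(nrow(twice)))
  four <- dplyr::bind_rows(twice, twice)
  four$subject_id <- sprintf("S%02d", seq_len(nrow(four)))
  expect_equal(relief_scores(twice)$weight, relief_scores(four)$weight,
               tolerance = 1e-12)
})

test_that("RELIEF is equivariant under feature permutation and warns on a
           singleton class", {
  tbl <- random_feature_table(n_per_class = 4, p = 5, shift = c(2, 1), seed = 6)
  perm <- c(3, 1, 5, 2, 4)
  tbl_perm <- tbl[c("subject_id", "label", feature_names(tbl)[perm])]
  w <- relief_scores(tbl)
  wp <- relief_scores(tbl_perm)
  expect_equal(wp$weight, w$weight[perm])

  single <- tbl[c(1:4, 5), ]
  expect_warning(relief_scores(single), "singleton")
})

test_that("the ranking filter keeps n_keep features deterministically", {
  tbl <- random_feature_table(n_per_class = 10, p = 50,
                              shift = rep(3, 5), seed = 7)
  cfg <- selection_config(n_keep = 25)
  kept <- rank_filter(tbl, cfg)
  expect_length(feature_names(kept), 25)
  # strongly planted features survive the cut
  expect_true(all(sprintf("f%02d", 1:5) %in% feature_names(kept)))
  expect_identical(feature_names(rank_filter(tbl, cfg)),
                   feature_names(kept))
  # n_keep >= p is the identity
  expect_identical(rank_filter(tbl, selection_config(n_keep = 50)), tbl)
})

test_that("the Mahalanobis criterion matches closed forms", {
  tbl <- tibble::tibble(
    subject_id = sprintf("S%d", 1:6),
    label = rep(c("continent", "incontinent"), each = 3),
    f1 = c(-1, 0, 1, 1, 2, 3)
  )
  # means 0 and 2, pooled variance 1: (mu1 - mu2)^2 / sigma^2 = 4
  expect_equal(mahalanobis_criterion(tbl, "f1"), 4)

  same <- tbl
  same$f1 <- c(-1, 0, 1, -1, 0, 1)
  expect_equal(mahalanobis_criterion(same, "f1"), 0)

  dup <- tbl
  dup$f2 <- dup$f1
  expect_error(mahalanobis_criterion(dup, c("f1", "f2")), "ridge")
  expect_error(mahalanobis_criterion(tbl, character()), "non-empty")
  expect_error(mahalanobis_criterion(tbl, "nope"), "Unknown feature")
})

test_that("adding a feature never decreases the criterion", {
  for (seed in 1:10) {
    tbl <- random_feature_table(n_per_class = 10, p = 6,
                                shift = c(1, 0.5, rep(0, 4)), seed = seed)
    fn <- feature_names(tbl)
    set.seed(seed)
    sub <- sample(fn, 3)
    extra <- setdiff(fn, sub)[1]
    expect_gte(mahalanobis_criterion(tbl, c(sub, extra)),
               mahalanobis_criterion(tbl, sub) - 1e-8)
  }
})

test_that("branch-and-bound returns the exhaustive optimum", {
  for (seed in 1:12) {
    p <- sample(8:12, 1)
    tbl <- random_feature_table(n_per_class = 8, p = p,
                                shift = stats::runif(p, -1, 1), seed = seed)
    cfg <- selection_config(n_keep = p, mahalanobis_ridge = 0)
    got <- branch_and_bound_select(tbl, 3, cfg)
    want <- exhaustive_best_subset(tbl, 3)
    expect_equal(got$criterion_value, want$criterion, tolerance = 1e-9)
    expect_setequal(got$selected, want$selected)
  }
})

test_that("branch-and-bound degenerates gracefully at d = p and validates d", {
  tbl <- random_feature_table(n_per_class = 6, p = 5, seed = 3)
  cfg <- selection_config(n_keep = 5, mahalanobis_ridge = 0)
  full <- branch_and_bound_select(tbl, 5, cfg)
  expect_setequal(full$selected, feature_names(tbl))
  expect_equal(full$criterion_value,
               oracle_criterion(tbl, feature_names(tbl)), tolerance = 1e-9)
  expect_error(branch_and_bound_select(tbl, 6, cfg), "exceeds")
  expect_error(
    branch_and_bound_select(random_feature_table(p = 30, seed = 1), 3,
                            selection_config(n_keep = 25)),
    "rank_filter"
  )
})

test_that("the selected subset's criterion is reproducible by re-evaluation", {
  tbl <- random_feature_table(n_per_class = 8, p = 10,
                              shift = c(2, 1, rep(0, 8)), seed = 9)
  cfg <- selection_config(n_keep = 10, mahalanobis_ridge = 0)
  bb <- branch_and_bound_select(tbl, 4, cfg)
  expect_equal(mahalanobis_criterion(tbl, bb$selected), bb$criterion_value,
               tolerance = 1e-9)
})

test_that("RFE follows the elimination schedule and is seed-deterministic", {
  tbl <- random_feature_table(n_per_class = 8, p = 12,
                              shift = c(3, 3, rep(0, 10)), seed = 11)
  cfg <- selection_config(rfe_step = 5, rfe_target_dim = 2, seed = 4)
  r <- rfe_select(tbl, cfg)
  expect_length(r$selected, 2)
  expect_equal(r$nodes_evaluated, 2)  # 12 -> 7 -> 2: two ensemble fits
  expect_identical(rfe_select(tbl, cfg)$selected, r$selected)

  ident <- rfe_select(tbl, selection_config(rfe_target_dim = 12))
  expect_setequal(ident$selected, feature_names(tbl))
})
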