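#' Classification metrics
#'
#' Accuracy `(TP + TN) / all`, precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)`, with the incontinent class as positive. A zero
#' denominator yields 0 with a warning.
#'
#' @param predicted,truth Character vectors of class labels, equal length.
#' @param positive Positive class label.
#' @return One-row tibble: `accuracy`, `precision`, `recall`.
#' @export
classification_metrics <- function(predicted, truth,
                                   positive = "incontinent") {
  if (length(predicted) != length(truth)) {
    rlang::abort("`predicted` and `truth` must have equal length.")
  }
  lv <- class_levels()
  if (!all(c(predicted, truth) %in% lv)) {
    rlang::abort(paste0("Labels must be one of: ", paste(lv, collapse = ", ")))
  }
  tp <- sum(predicted == positive & truth == positive)
  tn <- sum(predicted != positive & truth != positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      rlang::warn(paste0("Zero denominator for ", what, "; reporting 0."))
      return(0)
    }
    num / den
  }
  tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    precision = safe_div(tp, tp + fp, "precision"),
    recall = safe_div(tp, tp + fn, "recall")
  )
}

#' Inner leave-one-out configuration selection
#'
#' For every candidate configuration, leave-one-out validation accuracy over
#' the training set (features standardized with each inner fold's training
#' statistics). Returns the best configuration per model and overall, under
#' a deterministic tie-break: highest accuracy, then the simpler model
#' (larger k / smaller C), then fixed model order (knn, logistic, svm).
#'
#' @param train_table A feature table (both classes with >= 2 subjects).
#' @param grids A [default_model_grids()].
#' @return List with `overall` (one-row tibble `model`, `param`,
#'   `accuracy`), `per_model` and the full `accuracies` tibble.
#' @export
inner_loo_select <- function(train_table, grids = default_model_grids()) {
  x <- feature_matrix(train_table)
  y <- train_table$label
  if (min(table(y)) < 2) {
    rlang::abort("Inner LOO needs at least 2 training subjects per class.")
  }
  n <- nrow(x)
  configs <- enumerate_configs(grids)
  correct <- numeric(nrow(configs))
  for (i in seq_len(n)) {
    st <- scale_stats(x[-i, , drop = FALSE])
    xtr <- apply_scale(x[-i, , drop = FALSE], st)
    xte <- apply_scale(x[i, , drop = FALSE], st)
    pr <- predict_all_configs(xtr, y[-i], xte, grids)
    correct <- correct + (pr[1, ] == y[i])
  }
  acc <- tibble::tibble(
    model = configs$model, param = configs$param, accuracy = correct / n
  )
  # simplicity: larger k is simpler for knn, smaller C (stronger
  # regularization) for the linear models
  simplicity <- ifelse(acc$model == "knn", -acc$param, acc$param)
  per_model <- acc |>
    dplyr::mutate(.simp = simplicity) |>
    dplyr::group_by(.data$model) |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$.simp,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".simp")
  per_model <- per_model[order(match(per_model$model, model_order())), ]
  overall <- per_model[order(-per_model$accuracy,
                             match(per_model$model, model_order())), ][1, ]
  list(overall = overall, per_model = per_model, accuracies = acc)
}

apply_selection <- function(table, method, cfg, dim) {
  reduced <- rank_filter(table, cfg)
  sub <- switch(method,
    bb = branch_and_bound_select(reduced, dim, cfg),
    rfe = {
      cfg$rfe_target_dim <- as.integer(dim)
      rfe_select(reduced, cfg)
    },
    rlang::abort(paste0("Unknown selection method: ", method))
  )
  list(
    table = dplyr::select(table,
                          dplyr::all_of(c("subject_id", "label", sub$selected))),
    subset = sub
  )
}

#' Nested leave-one-out model selection and evaluation
#'
#' Outer leave-one-out over subjects; within each outer fold an inner
#' leave-one-out ([inner_loo_select()]) picks the best configuration per
#' model and overall, the chosen models predict the held-out subject, and
#' the per-fold choice is tallied as a selection frequency. Features are
#' standardized with training-fold statistics only.
#'
#' Feature selection can run once on the full table before the outer loop
#' (`selection_scope = "global"`, the optimistic variant in which the search
#' has seen every subject) or be recomputed inside every outer fold
#' (`"outer_fold"`, leakage-free; the held-out subject never influences
#' ranking, search or standardization).
#'
#' @param table A feature table (>= 4 subjects, both classes).
#' @param grids A [default_model_grids()].
#' @param selection `"none"`, `"bb"` or `"rfe"`.
#' @param selection_scope `"outer_fold"` or `"global"`.
#' @param cfg A [selection_config()].
#' @param subset_dim Target subset size for the search (default 6).
#' @return A `pf_evaluation`: list with `outer_predictions` (per-subject
#'   truth, fold-best and per-model predictions, chosen configuration,
#'   selected features), `metrics`, `selection_frequency`, and the settings.
#' @export
nested_loo_evaluate <- function(table, grids = default_model_grids(),
                                selection = c("none", "bb", "rfe"),
                                selection_scope = c("outer_fold", "global"),
                                cfg = selection_config(),
                                subset_dim = 6) {
  selection <- match.arg(selection)
  selection_scope <- match.arg(selection_scope)
  n <- nrow(table)
  if (n < 4) rlang::abort("Nested LOO needs at least 4 subjects.")
  if (min(base::table(table$label)) < 2) {
    rlang::abort("Nested LOO needs both classes with >= 2 subjects.")
  }

  global_sel <- NULL
  tbl_used <- table
  if (selection != "none" && selection_scope == "global") {
    global_sel <- apply_selection(table, selection, cfg, subset_dim)
    tbl_used <- global_sel$table
  }

  folds <- vector("list", n)
  for (i in seq_len(n)) {
    if (selection != "none" && selection_scope == "outer_fold") {
      sel_i <- apply_selection(table[-i, ], selection, cfg, subset_dim)
      train <- sel_i$table
      sel_feats <- sel_i$subset$selected
    } else {
      train <- tbl_used[-i, ]
      sel_feats <- feature_names(tbl_used)
    }
    if (min(base::table(train$label)) < 2) {
      rlang::abort(sprintf(
        "Outer fold %d leaves a near single-class training set.", i
      ))
    }
    pick <- inner_loo_select(train, grids)

    x <- feature_matrix(train)
    st <- scale_stats(x)
    xtr <- apply_scale(x, st)
    xte <- apply_scale(
      as.matrix(tbl_used[i, sel_feats, drop = FALSE])[, , drop = FALSE],
      st
    )
    preds <- vapply(seq_len(nrow(pick$per_model)), function(r) {
      predict_one_config(xtr, train$label, xte,
                         pick$per_model$model[r], pick$per_model$param[r])
    }, character(1))
    names(preds) <- pick$per_model$model
    best_pred <- preds[[pick$overall$model]]

    row <- tibble::tibble(
      subject_id = table$subject_id[i],
      truth = table$label[i],
      pred_best = best_pred,
      chosen_model = pick$overall$model,
      chosen_param = pick$overall$param,
      inner_accuracy = pick$overall$accuracy
    )
    for (m in model_order()) {
      row[[paste0("pred_", m)]] <-
        if (m %in% names(preds)) preds[[m]] else NA_character_
    }
    row$selected_features <- list(sel_feats)
    folds[[i]] <- row
  }
  outer <- dplyr::bind_rows(folds)

  tracked <- c("best", intersect(model_order(), names(grids)))
  metrics <- dplyr::bind_rows(lapply(tracked, function(m) {
    pr <- outer[[paste0("pred_", m)]]
    dplyr::bind_cols(tibble::tibble(model = m),
                     classification_metrics(pr, outer$truth))
  }))
  freq <- outer |>
    dplyr::count(.data$chosen_model, name = "count") |>
    dplyr::rename(model = "chosen_model")
  freq <- dplyr::left_join(
    tibble::tibble(model = intersect(model_order(), names(grids))),
    freq, by = "model"
  )
  freq$count[is.na(freq$count)] <- 0L
  freq$out_of <- n

  structure(
    list(outer_predictions = outer, metrics = metrics,
         selection_frequency = freq,
         settings = list(selection = selection,
                         selection_scope = selection_scope,
                         subset_dim = subset_dim, cfg = cfg, grids = grids),
         global_subset = global_sel$subset),
    class = "pf_evaluation"
  )
}

#' @exportS3Method base::print
print.pf_evaluation <- function(x, ...) {
  cat(sprintf(
    "<pf_evaluation> %d subjects | selection: %s (%s)\n",
    nrow(x$outer_predictions), x$settings$selection, x$settings$selection_scope
  ))
  print(x$metrics)
  invisible(x)
}

#' Feature selection frequency across outer folds
#'
#' @param report A `pf_evaluation` run with per-fold selection
#'   (`selection_scope = "outer_fold"`).
#' @return Tibble `feature`, `count`, `out_of`, most frequent first.
#' @export
feature_selection_frequency <- function(report) {
  stopifnot(inherits(report, "pf_evaluation"))
  n <- nrow(report$outer_predictions)
  feats <- unlist(report$outer_predictions$selected_features)
  out <- tibble::as_tibble(table(feature = feats), n = "count")
  out$count <- as.integer(out$count)
  out$out_of <- n
  dplyr::arrange(out, dplyr::desc(.data$count), .data$feature)
}

#' Combined four-maneuver subset table
#'
#' Per maneuver: ranking filter to `cfg$n_keep` features, then
#' branch-and-bound at dimension `dim`; the four selected subsets are
#' concatenated (feature names stay distinct through their maneuver tags)
#' into one table of `4 * dim` features.
#'
#' @param tables Named list of the four per-maneuver feature tables, sharing
#'   subject order and labels.
#' @param cfg A [selection_config()].
#' @param dim Per-maneuver output subset dimension (default 6, giving the
#'   24-feature combined table).
#' @return List with `table` (the combined feature table) and `subsets`
#'   (per-maneuver `pf_subset`s).
#' @export
combined_subset_table <- function(tables, cfg = selection_config(), dim = 6) {
  if (is.null(names(tables))) {
    names(tables) <- paste0("maneuver_", seq_along(tables))
  }
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$subject_id, ref$subject_id) ||
        !identical(t$label, ref$label)) {
      rlang::abort("All maneuver tables must share subject order and labels.")
    }
  }
  subsets <- purrr::map(tables, function(t) {
    branch_and_bound_select(rank_filter(t, cfg), dim, cfg)
  })
  feat_cols <- purrr::map2(tables, subsets, function(t, s) {
    t[s$selected]
  })
  combined <- dplyr::bind_cols(
    tibble::tibble(subject_id = ref$subject_id, label = ref$label),
    feat_cols
  )
  list(table = combined, subsets = subsets)
}

#' Combined four-maneuver search scheme
#'
#' Builds the concatenated 4 x `dim` feature table with
#' [combined_subset_table()], then feeds it to the remaining selection and
#' nested leave-one-out evaluation.
#'
#' @inheritParams combined_subset_table
#' @inheritParams nested_loo_evaluate
#' @return A `pf_combined`: list with `table`, `per_maneuver` subsets and
#'   the `report` (`pf_evaluation`).
#' @export
combined_scheme <- function(tables, grids = default_model_grids(),
                            selection = c("none", "bb", "rfe"),
                            selection_scope = c("outer_fold", "global"),
                            cfg = selection_config(), dim = 6,
                            subset_dim = 6) {
  selection <- match.arg(selection)
  selection_scope <- match.arg(selection_scope)
  ct <- combined_subset_table(tables, cfg, dim)
  report <- nested_loo_evaluate(ct$table, grids, selection = selection,
                                selection_scope = selection_scope,
                                cfg = cfg, subset_dim = subset_dim)
  structure(
    list(table = ct$table, per_maneuver = ct$subsets, report = report),
    class = "pf_combined"
  )
}

#' McNemar paired comparison of two classifiers
#'
#' Continuity-corrected McNemar statistic `(|b - c| - 1)^2 / (b + c)` on the
#' discordant counts (b: A correct and B wrong; c: the reverse), referred to
#' a chi-square distribution with 1 df. With `exact = TRUE` the two-sided
#' exact binomial p-value on the discordant pairs is used instead
#' (recommended when `b + c` is small). Identical error patterns
#' (`b + c = 0`) give statistic 0 and p 1 by convention.
#'
#' @param preds_a,preds_b Aligned prediction vectors.
#' @param truth True labels.
#' @param exact Use the exact binomial variant.
#' @return One-row tibble: `b`, `c`, `statistic`, `p_value`, `method`.
#' @export
mcnemar_compare <- function(preds_a, preds_b, truth, exact = FALSE) {
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth)) {
    rlang::abort("Prediction vectors must align with `truth`.")
  }
  ok_a <- preds_a == truth
  ok_b <- preds_b == truth
  b <- sum(ok_a & !ok_b)
  c_ <- sum(!ok_a & ok_b)
  if (b + c_ == 0) {
    return(tibble::tibble(b = b, c = c_, statistic = 0, p_value = 1,
                          method = if (exact) "exact" else "chisq_cc"))
  }
  if (exact) {
    p <- stats::binom.test(b, b + c_, 0.5)$p.value
    stat <- min(b, c_)
  } else {
    stat <- (abs(b - c_) - 1)^2 / (b + c_)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(b = b, c = c_, statistic = stat, p_value = p,
                 method = if (exact) "exact" else "chisq_cc")
}

#' Pairwise McNemar tests between the tracked models of a report
#'
#' @param report A `pf_evaluation`.
#' @param exact Passed to [mcnemar_compare()].
#' @return Tibble with one row per model pair.
#' @export
pairwise_model_tests <- function(report, exact = FALSE) {
  stopifnot(inherits(report, "pf_evaluation"))
  outer <- report$outer_predictions
  models <- intersect(model_order(), names(report$settings$grids))
  pairs <- utils::combn(models, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(p) {
    dplyr::bind_cols(
      tibble::tibble(model_a = p[1], model_b = p[2]),
      mcnemar_compare(outer[[paste0("pred_", p[1])]],
                      outer[[paste0("pred_", p[2])]],
                      outer$truth, exact = exact)
    )
  }))
}

#' Distribution report for the top-selected features
#'
#' For each requested feature: Shapiro-Wilk normality p-value per class, the
#' two-sided Mann-Whitney (Wilcoxon rank-sum) p-value between classes, and
#' per-class medians and IQRs (box-plot-ready summaries).
#'
#' @param table A feature table.
#' @param features Character vector of feature names to report.
#' @return Tibble with one row per feature.
#' @export
top_feature_report <- function(table, features) {
  missing <- setdiff(features, feature_names(table))
  if (length(missing)) {
    rlang::abort(paste0("Unknown feature(s): ", paste(missing, collapse = ", ")))
  }
  is_con <- table$label == "continent"
  shapiro_p <- function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
  }
  dplyr::bind_rows(lapply(features, function(f) {
    v <- table[[f]]
    wt <- suppressWarnings(
      stats::wilcox.test(v[!is_con], v[is_con], alternative = "two.sided")
    )
    tibble::tibble(
      feature = f,
      shapiro_p_continent = shapiro_p(v[is_con]),
      shapiro_p_incontinent = shapiro_p(v[!is_con]),
      mannwhitney_p = wt$p.value,
      median_continent = stats::median(v[is_con]),
      iqr_continent = stats::IQR(v[is_con]),
      median_incontinent = stats::median(v[!is_con]),
      iqr_incontinent = stats::IQR(v[!is_con])
    )
  }))
}

#' Two-component PCA projection
#'
#' Standardized features projected on the top two principal components, for
#' visualizing class separability. Zero-variance features are dropped with a
#' warning before scaling.
#'
#' @param table A feature table with >= 2 features.
#' @return A `pf_pca` tibble: `subject_id`, `label`, `PC1`, `PC2`, with the
#'   explained-variance fractions in the `"explained"` attribute.
#' @export
pca_projection <- function(table) {
  x <- feature_matrix(table)
  if (ncol(x) < 2) rlang::abort("PCA projection needs at least 2 features.")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste0("Dropping zero-variance feature(s): ",
                       paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k == 1) scores <- cbind(scores, PC2 = 0)
  out <- tibble::tibble(
    subject_id = table$subject_id,
    label = table$label,
    PC1 = scores[, 1],
    PC2 = scores[, 2]
  )
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  attr(out, "explained") <- expl
  class(out) <- c("pf_pca", class(out))
  out
}
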