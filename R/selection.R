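#' Feature selection configuration
#'
#' Two-stage selection: a ranking filter keeping the `n_keep` most relevant
#' features (Pearson, RELIEF or their average rank), followed by either the
#' branch-and-bound subset search under the Mahalanobis class-separability
#' criterion or recursive feature elimination (RFE) driven by random-forest
#' impurity importance.
#'
#' @param n_keep Features kept by the ranking stage (default 25).
#' @param ranking_method `"average_rank"` (default), `"pearson"` or
#'   `"relief"`.
#' @param bb_dims Candidate subset sizes for branch-and-bound (default
#'   `1:min(6, n_keep)`; the combined scheme fixes 6).
#' @param rfe_step Features discarded per RFE round (default 5).
#' @param rfe_target_dim Features surviving RFE (default 6).
#' @param n_estimators,min_samples_split,max_features Tree-ensemble
#'   parameters for RFE importance: 10 trees, fully grown (minimum split
#'   size 2, i.e. terminal node size 1) with half the features tried per
#'   split.
#' @param seed Seed of the tree ensemble (recorded in results).
#' @param mahalanobis_ridge Ridge added to the pooled covariance as
#'   `ridge * I`; `NULL` uses `1e-8 * trace / p`, guarding near-singular
#'   pooled covariances at 25 features and ~47 training subjects.
#' @return A `pf_selection_config` list.
#' @export
selection_config <- function(n_keep = 25,
                             ranking_method = c("average_rank", "pearson",
                                                "relief"),
                             bb_dims = NULL,
                             rfe_step = 5, rfe_target_dim = 6,
                             n_estimators = 10, min_samples_split = 2,
                             max_features = 0.5, seed = 1,
                             mahalanobis_ridge = NULL) {
  ranking_method <- match.arg(ranking_method)
  if (rfe_step < 1) rlang::abort("`rfe_step` must be >= 1.")
  if (is.null(bb_dims)) bb_dims <- seq_len(min(6, n_keep))
  if (any(bb_dims < 1) || any(bb_dims > n_keep)) {
    rlang::abort("`bb_dims` must satisfy 1 <= dim <= n_keep.")
  }
  structure(
    list(n_keep = as.integer(n_keep), ranking_method = ranking_method,
         bb_dims = as.integer(bb_dims), rfe_step = as.integer(rfe_step),
         rfe_target_dim = as.integer(rfe_target_dim),
         n_estimators = as.integer(n_estimators),
         min_samples_split = as.integer(min_samples_split),
         max_features = max_features, seed = as.integer(seed),
         mahalanobis_ridge = mahalanobis_ridge),
    class = "pf_selection_config"
  )
}

label_01 <- function(label) {
  lv <- c("continent", "incontinent")
  if (!all(label %in% lv)) {
    rlang::abort("Labels must be 'continent' or 'incontinent'.")
  }
  as.numeric(label == "incontinent")
}

feature_matrix <- function(table) {
  as.matrix(table[feature_names(table)])
}

#' Pearson relevance scores
#'
#' Absolute Pearson correlation between each feature and the class label
#' encoded 0/1 (positive class: incontinent). Constant features score 0.
#'
#' @param table A feature table.
#' @return Tibble `feature`, `score`, in table column order.
#' @export
pearson_scores <- function(table) {
  y <- label_01(table$label)
  x <- feature_matrix(table)
  sds <- apply(x, 2, stats::sd)
  score <- rep(0, ncol(x))
  ok <- sds > 0 & stats::sd(y) > 0
  if (any(ok)) {
    score[ok] <- abs(suppressWarnings(stats::cor(x[, ok, drop = FALSE], y)))
  }
  tibble::tibble(feature = colnames(x), score = as.numeric(score))
}

#' RELIEF relevance weights
#'
#' Classic binary Relief with a deterministic full pass over the subjects:
#' features are min-max scaled to `[0, 1]`; for each subject the nearest hit
#' (same class) and nearest miss (other class) are found by Euclidean
#' distance over all candidate features, and each feature's weight is
#' incremented by `diff(f, x, miss) - diff(f, x, hit)`, finally normalized
#' by the number of completed iterations. A subject whose class has no other
#' member is skipped with a warning.
#'
#' @param table A feature table with both classes present.
#' @return Tibble `feature`, `weight`.
#' @export
relief_scores <- function(table) {
  y <- table$label
  if (length(unique(y)) < 2) {
    rlang::abort("RELIEF needs both classes present.")
  }
  x <- feature_matrix(table)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  xs <- sweep(sweep(x, 2, rng[1, ]), 2, span, "/")
  n <- nrow(xs)
  d2 <- as.matrix(stats::dist(xs))^2
  w <- numeric(ncol(xs))
  used <- 0L
  skipped <- character()
  for (i in seq_len(n)) {
    hits <- which(y == y[i])
    hits <- hits[hits != i]
    if (!length(hits)) {
      skipped <- c(skipped, table$subject_id[i])
      next
    }
    misses <- which(y != y[i])
    hit <- hits[which.min(d2[i, hits])]
    miss <- misses[which.min(d2[i, misses])]
    w <- w + abs(xs[i, ] - xs[miss, ]) - abs(xs[i, ] - xs[hit, ])
    used <- used + 1L
  }
  if (length(skipped)) {
    rlang::warn(paste0(
      "RELIEF skipped subject(s) with a singleton class: ",
      paste(skipped, collapse = ", ")
    ))
  }
  tibble::tibble(feature = colnames(x), weight = as.numeric(w / used))
}

#' Ranking filter
#'
#' Keeps the `n_keep` most relevant features by the configured ranking
#' method. `average_rank` averages the Pearson and RELIEF rank positions;
#' ties are broken by the Pearson rank, then by feature name, so the output
#' is deterministic. Columns are returned in ranked order.
#'
#' @param table A feature table.
#' @param cfg A [selection_config()].
#' @return The reduced feature table.
#' @export
rank_filter <- function(table, cfg = selection_config()) {
  fn <- feature_names(table)
  if (cfg$n_keep >= length(fn)) return(table)
  ps <- pearson_scores(table)
  p_rank <- rank(-ps$score, ties.method = "average")
  key <- switch(cfg$ranking_method,
    pearson = p_rank,
    relief = rank(-relief_scores(table)$weight, ties.method = "average"),
    average_rank = (p_rank +
      rank(-relief_scores(table)$weight, ties.method = "average")) / 2
  )
  ord <- order(key, p_rank, ps$feature)
  keep <- ps$feature[ord][seq_len(cfg$n_keep)]
  dplyr::select(table, dplyr::all_of(c("subject_id", "label", keep)))
}

pooled_class_stats <- function(table, features = feature_names(table)) {
  x <- as.matrix(table[features])
  g <- table$label
  x1 <- x[g == "continent", , drop = FALSE]
  x2 <- x[g == "incontinent", , drop = FALSE]
  n1 <- nrow(x1)
  n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) {
    rlang::abort("Need at least 2 subjects per class for the pooled covariance.")
  }
  s <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  list(d = colMeans(x1) - colMeans(x2), s = s, features = features)
}

default_ridge <- function(s, ridge) {
  if (!is.null(ridge)) return(ridge)
  1e-8 * mean(diag(s))
}

#' Mahalanobis class-separability criterion
#'
#' Squared Mahalanobis distance between the two class means under the pooled
#' within-class covariance, restricted to a feature subset. The criterion is
#' monotone non-decreasing under feature addition (at `ridge = 0`), which is
#' what licenses the branch-and-bound optimality guarantee.
#'
#' @param table A feature table.
#' @param subset Character vector of feature names (non-empty).
#' @param ridge Non-negative ridge added as `ridge * I` to the pooled
#'   covariance before inversion (default 0).
#' @return Non-negative scalar criterion value.
#' @export
mahalanobis_criterion <- function(table, subset, ridge = 0) {
  if (!length(subset)) rlang::abort("`subset` must be non-empty.")
  missing <- setdiff(subset, feature_names(table))
  if (length(missing)) {
    rlang::abort(paste0("Unknown feature(s): ", paste(missing, collapse = ", ")))
  }
  st <- pooled_class_stats(table, subset)
  s <- st$s + diag(ridge, length(subset))
  sol <- tryCatch(solve(s, st$d), error = function(e) NULL)
  if (is.null(sol)) {
    rlang::abort(paste0(
      "Pooled within-class covariance is singular for this subset; ",
      "supply a positive `ridge`."
    ))
  }
  drop(crossprod(st$d, sol))
}

new_subset_result <- function(selected, criterion_value, nodes_evaluated,
                              method, seed = NA_integer_) {
  structure(
    list(selected = selected, criterion_value = criterion_value,
         nodes_evaluated = as.integer(nodes_evaluated), method = method,
         seed = seed),
    class = "pf_subset"
  )
}

#' @exportS3Method base::print
print.pf_subset <- function(x, ...) {
  cat(sprintf("<pf_subset> %s | %d feature(s) | criterion %.4g | %d node(s)\n",
              x$method, length(x$selected), x$criterion_value,
              x$nodes_evaluated))
  cat(paste0("  ", x$selected, collapse = "\n"), "\n")
  invisible(x)
}

#' Branch-and-bound subset search
#'
#' Complete, non-exhaustive search for the size-`d` feature subset
#' maximizing the Mahalanobis criterion. Monotonicity of the criterion under
#' feature deletion makes the bound exact, so the returned subset is the
#' global optimum; the node count never exceeds the exhaustive enumeration.
#' A greedy backward-elimination incumbent is computed first to tighten the
#' bound from the start.
#'
#' @param table A feature table (normally already reduced by
#'   [rank_filter()]; at most `cfg$n_keep` features are accepted).
#' @param d Target subset size.
#' @param cfg A [selection_config()].
#' @return A `pf_subset` with `selected` (names), `criterion_value`,
#'   `nodes_evaluated` and `method = "bb"`.
#' @export
branch_and_bound_select <- function(table, d, cfg = selection_config()) {
  fn <- feature_names(table)
  p <- length(fn)
  if (d > p) rlang::abort("`d` exceeds the number of features.")
  if (d < 1) rlang::abort("`d` must be >= 1.")
  if (p > cfg$n_keep) {
    rlang::abort(paste0(
      "Branch-and-bound accepts at most n_keep = ", cfg$n_keep,
      " features; apply rank_filter() first."
    ))
  }
  st <- pooled_class_stats(table)
  ridge <- default_ridge(st$s, cfg$mahalanobis_ridge)
  s <- st$s + diag(ridge, p)
  res <- bb_search_cpp(s, st$d, as.integer(d))
  new_subset_result(fn[res$selected], res$criterion, res$nodes, "bb")
}

#' Recursive feature elimination with random-forest importance
#'
#' Repeatedly fits a seeded random forest on the surviving features, ranks
#' them by mean impurity decrease, and discards the `rfe_step` lowest-ranked
#' (fewer on the final round) until `rfe_target_dim` remain. Ties in
#' importance are broken by column order. The stored `criterion_value` is
#' the Mahalanobis criterion of the selected subset, so the result can be
#' re-scored independently of the ensemble.
#'
#' @param table A feature table.
#' @param cfg A [selection_config()].
#' @return A `pf_subset` with `method = "rfe"`.
#' @export
rfe_select <- function(table, cfg = selection_config()) {
  if (cfg$rfe_target_dim < 1) rlang::abort("`rfe_target_dim` must be >= 1.")
  surviving <- feature_names(table)
  y <- factor(table$label, levels = c("continent", "incontinent"))
  fits <- 0L
  round_i <- 0L
  while (length(surviving) > cfg$rfe_target_dim) {
    round_i <- round_i + 1L
    x <- as.matrix(table[surviving])
    set.seed(cfg$seed + round_i)
    rf <- randomForest::randomForest(
      x = x, y = y,
      ntree = cfg$n_estimators,
      mtry = max(1L, floor(cfg$max_features * ncol(x))),
      nodesize = if (cfg$min_samples_split <= 2) 1L
                 else cfg$min_samples_split %/% 2L,
      importance = FALSE
    )
    fits <- fits + 1L
    imp <- randomForest::importance(rf, type = 2)[, 1]
    k <- min(cfg$rfe_step, length(surviving) - cfg$rfe_target_dim)
    drop_idx <- order(imp, seq_along(imp))[seq_len(k)]
    surviving <- surviving[-drop_idx]
  }
  st <- pooled_class_stats(table, feature_names(table))
  crit <- mahalanobis_criterion(
    table, surviving, ridge = default_ridge(st$s, cfg$mahalanobis_ridge)
  )
  new_subset_result(surviving, crit, fits, "rfe", seed = cfg$seed)
}
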