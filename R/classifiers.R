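#' Classifier hyperparameter grids
#'
#' One scanned hyperparameter per model: the neighbor count k for k-NN
#' (odd values 1-25, avoiding voting ties), and the inverse regularization
#' strength C for logistic regression (`0.0001, 0.001, 0.005, 0.01, 0.05,
#' 0.1`) and the linear-kernel SVM (`0.0001, 0.001, 0.005, 0.01, 0.05`).
#'
#' @param knn_k,logistic_C,svm_C Numeric value grids; set an entry to `NULL`
#'   to drop that model.
#' @return A `pf_model_grids` list.
#' @export
default_model_grids <- function(knn_k = seq(1, 25, by = 2),
                                logistic_C = c(1e-4, 1e-3, 5e-3, 0.01, 0.05,
                                               0.1),
                                svm_C = c(1e-4, 1e-3, 5e-3, 0.01, 0.05)) {
  grids <- list(knn = knn_k, logistic = logistic_C, svm = svm_C)
  grids <- grids[!vapply(grids, is.null, TRUE)]
  if (!length(grids)) rlang::abort("At least one model grid is required.")
  structure(grids, class = "pf_model_grids")
}

model_order <- function() c("knn", "logistic", "svm")

enumerate_configs <- function(grids) {
  dplyr::bind_rows(lapply(names(grids), function(m) {
    tibble::tibble(model = m, param = as.numeric(grids[[m]]))
  }))
}

scale_stats <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_scale <- function(x, st) {
  sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
}

class_levels <- function() c("continent", "incontinent")

# Predictions of every configuration on the test rows; train features are
# assumed standardized and the test rows standardized with the same stats.
# Returns a character matrix [n_test x n_configs] aligned with
# enumerate_configs(grids).
predict_all_configs <- function(xtr, ytr, xte, grids) {
  ytr <- factor(ytr, levels = class_levels())
  out <- list()
  for (m in names(grids)) {
    vals <- grids[[m]]
    pr <- switch(m,
      knn = vapply(vals, function(k) {
        as.character(class::knn(xtr, xte, ytr,
                                k = min(k, nrow(xtr)), use.all = TRUE))
      }, character(nrow(xte))),
      logistic = predict_logistic_grid(xtr, ytr, xte, vals),
      svm = vapply(vals, function(C) {
        fit <- e1071::svm(x = xtr, y = ytr, kernel = "linear", cost = C,
                          scale = FALSE)
        as.character(stats::predict(fit, xte))
      }, character(nrow(xte)))
    )
    out[[m]] <- matrix(pr, nrow = nrow(xte))
  }
  do.call(cbind, out)
}

# Ridge-penalized logistic regression via glmnet, matching the inverse
# regularization strength parameterisation: lambda = 1 / (n * C). The whole
# C grid is fitted as one regularization path.
predict_logistic_grid <- function(xtr, ytr, xte, c_grid) {
  n <- nrow(xtr)
  if (ncol(xtr) < 2) {  # glmnet requires >= 2 columns; pad an inert one
    xtr <- cbind(xtr, 0)
    xte <- cbind(xte, 0)
  }
  lambdas <- 1 / (n * c_grid)
  path <- sort(unique(c(lambdas, max(lambdas) * c(2, 4))), decreasing = TRUE)
  # glmnet warns about class counts < 8 on every leave-one-out fold; that is
  # the expected operating regime here
  fit <- suppressWarnings(
    glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                   lambda = path, standardize = FALSE)
  )
  pr <- stats::predict(fit, xte, s = lambdas, type = "class", exact = FALSE)
  matrix(as.character(pr), nrow = nrow(xte))
}

# Fit one configuration on the full training fold and predict test rows.
predict_one_config <- function(xtr, ytr, xte, model, param) {
  grids <- stats::setNames(list(param), model)
  pr <- predict_all_configs(xtr, ytr, xte, grids)
  pr[, 1]
}
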