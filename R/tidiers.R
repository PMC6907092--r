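#' Tidy and glance methods
#'
#' Broom-style summaries of fitted objects: `tidy()` returns the per-unit
#' table (metrics per model, features of a subset, per-feature selection
#' counts), `glance()` a one-row overview.
#'
#' @param x A `pf_evaluation`, `pf_subset` or `pf_combined`.
#' @param ... Unused.
#' @return A tibble.
#' @name pfpress-tidiers
NULL

#' @rdname pfpress-tidiers
#' @export
tidy.pf_evaluation <- function(x, ...) {
  dplyr::left_join(x$metrics,
                   dplyr::rename(x$selection_frequency,
                                 selection_count = "count"),
                   by = "model")
}

#' @rdname pfpress-tidiers
#' @export
glance.pf_evaluation <- function(x, ...) {
  best <- x$metrics[x$metrics$model == "best", ]
  modal <- x$selection_frequency$model[which.max(x$selection_frequency$count)]
  tibble::tibble(
    n_subjects = nrow(x$outer_predictions),
    accuracy = best$accuracy,
    precision = best$precision,
    recall = best$recall,
    modal_model = modal,
    selection = x$settings$selection,
    selection_scope = x$settings$selection_scope
  )
}

#' @rdname pfpress-tidiers
#' @export
tidy.pf_subset <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$selected), feature = x$selected)
}

#' @rdname pfpress-tidiers
#' @export
glance.pf_subset <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_selected = length(x$selected),
    criterion_value = x$criterion_value,
    nodes_evaluated = x$nodes_evaluated
  )
}

#' @rdname pfpress-tidiers
#' @export
tidy.pf_combined <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$per_maneuver), function(m) {
    dplyr::bind_cols(tibble::tibble(maneuver = m),
                     tidy(x$per_maneuver[[m]]))
  }))
}

#' @rdname pfpress-tidiers
#' @export
glance.pf_combined <- function(x, ...) {
  g <- glance(x$report)
  g$n_features <- length(feature_names(x$table))
  g
}
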