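#' Plot a PCA projection
#'
#' Scatter of the two principal-component scores colored by class, with the
#' explained-variance fractions on the axis labels.
#'
#' @param object A `pf_pca` from [pca_projection()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pf_pca <- function(object, ...) {
  expl <- attr(object, "explained")
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", i,
            100 * if (length(expl) >= i) expl[i] else 0)
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$label,
                               shape = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Selection-frequency bar chart of a report
#'
#' @param report A `pf_evaluation`.
#' @return A ggplot of per-model selection counts across outer folds.
#' @export
plot_selection_frequency <- function(report) {
  stopifnot(inherits(report, "pf_evaluation"))
  df <- report$selection_frequency
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL,
                  y = sprintf("times selected (out of %d)", df$out_of[1])) +
    ggplot2::theme_minimal()
}

#' Box plots of the top-selected features by class
#'
#' @param table A feature table.
#' @param features Feature names to plot.
#' @return A ggplot with one facet per feature.
#' @export
plot_top_features <- function(table, features) {
  df <- tidyr::pivot_longer(
    dplyr::select(table, dplyr::all_of(c("label", features))),
    dplyr::all_of(features),
    names_to = "feature", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$value,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Mean activation trace of a recording
#'
#' @param recording A `pf_recording`.
#' @return A ggplot of the whole-matrix mean pressure over time.
#' @export
plot_recording_trace <- function(recording) {
  stopifnot(inherits(recording, "pf_recording"))
  d <- dim(recording$values)
  df <- tibble::tibble(
    t = (seq_len(d[1]) - 1) / recording$fs,
    kpa = rowMeans(matrix(recording$values, nrow = d[1]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$kpa)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = recording$baseline_s,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "mean pressure (kPa)",
                  title = sprintf("%s | %s | %s", recording$subject_id,
                                  recording$label, recording$maneuver)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
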