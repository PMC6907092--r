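#' Activation threshold configuration
#'
#' The activation instant is the first instant at which the peak series
#' exceeds a threshold derived from the pre-command rest segment:
#' `delta = baseline mean + delta_multiplier * baseline SD` of the peak
#' series. The mean offset keeps the threshold above resting pressure; with
#' `use_baseline_mean = FALSE` the threshold is the bare multiple of the SD.
#'
#' @param baseline_window_s Duration (s) of the rest segment used as the base
#'   value; must be positive and shorter than the recording.
#' @param delta_multiplier Multiplier on the baseline SD (default 2).
#' @param use_baseline_mean Add the baseline mean to the threshold.
#' @return A `pf_activation_config` list.
#' @export
activation_config <- function(baseline_window_s = 1, delta_multiplier = 2,
                              use_baseline_mean = TRUE) {
  if (baseline_window_s <= 0) {
    rlang::abort("`baseline_window_s` must be > 0.")
  }
  structure(
    list(baseline_window_s = baseline_window_s,
         delta_multiplier = delta_multiplier,
         use_baseline_mean = use_baseline_mean),
    class = "pf_activation_config"
  )
}

# Split a pf_series into baseline and maneuver-window sample indices.
series_windows <- function(gs, act) {
  n <- length(gs$y_peak)
  n_base <- round(min(act$baseline_window_s, gs$baseline_s) * gs$fs)
  if (n_base >= n) {
    rlang::abort("Baseline window covers the whole series.")
  }
  list(base = seq_len(n_base), win = seq(n_base + 1, n))
}

# Normalized time of the i-th sample of a window of length nw: first sample
# maps to 0, last to 1.
norm_time <- function(i, nw) if (nw > 1) (i - 1) / (nw - 1) else 0

#' Extremum features of a grouping series
#'
#' Maximum of the peak and sum series, their (normalized) instants, and the
#' activation instant, all computed on the post-baseline maneuver window.
#' Instants are normalized to `[0, 1]` over the window; the argmax takes the
#' earliest index on ties. `t_activ` is `NA` when the peak series never
#' exceeds the threshold (imputation happens at assembly, see
#' [extract_maneuver_features()]).
#'
#' @param gs A `pf_series` from [grouping_series()].
#' @param act An [activation_config()].
#' @return One-row tibble: `max_p`, `max_s`, `t_max_p`, `t_max_s`, `t_activ`.
#' @export
extremum_features <- function(gs, act = activation_config()) {
  w <- series_windows(gs, act)
  yp <- gs$y_peak[w$win]
  ys <- gs$y_sum[w$win]
  nw <- length(yp)
  ip <- which.max(yp)
  is <- which.max(ys)

  base <- gs$y_peak[w$base]
  delta <- act$delta_multiplier * stats::sd(base)
  if (length(base) < 2) delta <- NA_real_
  if (act$use_baseline_mean) delta <- delta + mean(base)
  ia <- if (is.na(delta)) NA_integer_ else which(yp > delta)[1]

  tibble::tibble(
    max_p = max(yp),
    max_s = max(ys),
    t_max_p = norm_time(ip, nw),
    t_max_s = norm_time(is, nw),
    t_activ = if (is.na(ia)) NA_real_ else norm_time(ia, nw)
  )
}

#' Pressure integrals of a grouping series
#'
#' Raw sample sums of the peak and sum series over the maneuver window (the
#' printed formulas sum samples; no 1/fs rescaling).
#'
#' @inheritParams extremum_features
#' @return One-row tibble: `int_p`, `int_s` (kPa x samples).
#' @export
integral_features <- function(gs, act = activation_config()) {
  w <- series_windows(gs, act)
  tibble::tibble(
    int_p = sum(gs$y_peak[w$win]),
    int_s = sum(gs$y_sum[w$win])
  )
}

#' Plateau duration of a grouping series
#'
#' Length, in seconds, of the longest contiguous interval of the maneuver
#' window on which the peak series stays at or above 90% of its maximum.
#' Invariant to positive rescaling of the series.
#'
#' @inheritParams extremum_features
#' @return Plateau duration in seconds.
#' @export
plateau_duration <- function(gs, act = activation_config()) {
  w <- series_windows(gs, act)
  yp <- gs$y_peak[w$win]
  above <- yp >= 0.9 * max(yp)
  r <- rle(above)
  max(r$lengths[r$values], 0) / gs$fs
}

#' Contraction and relaxation rates of the wave maneuver
#'
#' On normalized window time t' in `[0, 1]`:
#' contraction rate `CR = (max - value at t' = 0) / argmax`, relaxation rate
#' `RR = (value at t' = 1 - max) / (1 - argmax)`. A rate whose denominator
#' vanishes (argmax at the window boundary) is `NA` here and imputed with 0
#' at assembly.
#'
#' @inheritParams extremum_features
#' @return One-row tibble: `cr`, `rr` (kPa per unit normalized time).
#' @export
wave_rates <- function(gs, act = activation_config()) {
  w <- series_windows(gs, act)
  yp <- gs$y_peak[w$win]
  nw <- length(yp)
  i <- which.max(yp)
  tm <- norm_time(i, nw)
  tibble::tibble(
    cr = if (tm > 0) (yp[i] - yp[1]) / tm else NA_real_,
    rr = if (tm < 1) (yp[nw] - yp[i]) / (1 - tm) else NA_real_
  )
}

# Documented fixed order of the quadrant x band intersection groupings used
# by the covariance features.
intersection_order <- function(catalog) names(catalog$s_long_x_s_lat)

#' Covariance features over the quadrant-by-band intersections
#'
#' Sample covariance matrix (denominator n - 1) of the twelve sum series of
#' the `s_long_x_s_lat` superset over the maneuver window; emits the 12 main
#' diagonal entries and, by default, the 11 first-subdiagonal entries (23
#' features). Computed for the maximal contraction, Valsalva and endurance
#' maneuvers.
#'
#' @param recording A filtered `pf_recording`.
#' @param catalog A `pf_catalog`.
#' @param act An [activation_config()].
#' @param n_subdiagonals Number of subdiagonals below the main diagonal to
#'   emit (default 1; the printed plural is ambiguous, so this is
#'   configurable).
#' @return One-row tibble of named covariance features.
#' @export
covariance_features <- function(recording, catalog,
                                act = activation_config(),
                                n_subdiagonals = 1) {
  stopifnot(inherits(recording, "pf_recording"), inherits(catalog, "pf_catalog"))
  if (!recording$maneuver %in% c("max_contraction", "valsalva", "endurance")) {
    rlang::abort(paste0(
      "Covariance features are defined for the maximal contraction, ",
      "Valsalva and endurance maneuvers, not ", recording$maneuver, "."
    ))
  }
  gnames <- intersection_order(catalog)
  series <- lapply(gnames, function(g) {
    gs <- grouping_series(recording, catalog$s_long_x_s_lat[[g]], g)
    w <- series_windows(gs, act)
    gs$y_sum[w$win]
  })
  x <- do.call(cbind, series)
  if (nrow(x) < 2) {
    rlang::abort("Covariance features need at least two time samples.")
  }
  cv <- stats::cov(x)
  vals <- diag(cv)
  names(vals) <- paste0("cov.", gnames, ".", gnames)
  for (k in seq_len(n_subdiagonals)) {
    idx <- seq_len(length(gnames) - k)
    sub <- cv[cbind(idx + k, idx)]
    names(sub) <- paste0("cov.", gnames[idx + k], ".", gnames[idx])
    vals <- c(vals, sub)
  }
  tibble::as_tibble(as.list(vals))
}

# Fixed flat grouping order: quadrants, bands, planes, rings, intersections,
# whole matrix (35 groupings).
flat_groupings <- function(catalog) {
  out <- list()
  for (ss in c("s_long", "s_lat", "planes", "rings", "s_long_x_s_lat",
               "whole_matrix")) {
    for (g in names(catalog[[ss]])) {
      out[[length(out) + 1L]] <- list(superset = ss, grouping = g,
                                      members = catalog[[ss]][[g]])
    }
  }
  out
}

#' Per-maneuver feature menu counts
#'
#' @return Named integer vector of expected feature counts per maneuver:
#'   5 variables x 35 groupings + 23 covariance features for the maximal
#'   contraction and Valsalva maneuvers; the same plus integrals over planes
#'   and rings and the plateau for endurance; 5 variables x 35 groupings +
#'   the two wave rates for the wave maneuver.
#' @export
feature_menu_counts <- function() {
  c(max_contraction = 5L * 35L + 23L,
    valsalva = 5L * 35L + 23L,
    endurance = 5L * 35L + 23L + 2L * 15L + 1L,
    wave = 5L * 35L + 2L)
}

#' Extract the full feature vector of one recording
#'
#' Assembles the maneuver-specific feature menu over the six supersets:
#' * maximal contraction, Valsalva: `max_p`, `max_s`, `t_max_p`, `t_max_s`,
#'   `t_activ` over all 35 groupings, plus 23 covariance features;
#' * endurance: the above plus `int_p`, `int_s` over planes and rings and
#'   the whole-matrix `plateau`;
#' * wave: `max_p`, `t_max_p`, `int_p`, `int_s`, `t_activ` over all 35
#'   groupings, plus the whole-matrix `cr` and `rr`.
#'
#' Feature names follow `maneuver.superset.grouping.variable`. Undefined
#' values (`t_activ` never crossing the threshold; a wave rate with a
#' boundary argmax) are imputed with the window boundary (`t_activ = 1`,
#' rates `= 0`); imputed names are attached as the `"imputed"` attribute and
#' reported with a message unless `quiet = TRUE`.
#'
#' @param recording A filtered `pf_recording` (see [filter_recording()]).
#' @param catalog A `pf_catalog`.
#' @param act An [activation_config()].
#' @param quiet Suppress the imputation message.
#' @return One-row tibble of named features.
#' @export
extract_maneuver_features <- function(recording, catalog,
                                      act = activation_config(),
                                      quiet = TRUE) {
  stopifnot(inherits(recording, "pf_recording"), inherits(catalog, "pf_catalog"))
  if (!isTRUE(recording$filtered)) {
    rlang::abort(
      "Recording must be filtered per sensor first; see filter_recording()."
    )
  }
  m <- recording$maneuver
  groupings <- flat_groupings(catalog)
  ext_vars <- if (m == "wave") {
    c("max_p", "t_max_p", "t_activ")
  } else {
    c("max_p", "max_s", "t_max_p", "t_max_s", "t_activ")
  }

  pieces <- list()
  for (g in groupings) {
    gs <- grouping_series(recording, g$members, g$grouping)
    ex <- extremum_features(gs, act)
    vals <- ex[ext_vars]
    if (m == "wave") {
      vals <- cbind(vals, integral_features(gs, act))
    }
    if (m == "endurance" && g$superset %in% c("planes", "rings")) {
      vals <- cbind(vals, integral_features(gs, act))
    }
    if (g$superset == "whole_matrix") {
      if (m == "endurance") {
        vals$plateau <- plateau_duration(gs, act)
      }
      if (m == "wave") {
        vals <- cbind(vals, wave_rates(gs, act))
      }
    }
    names(vals) <- paste(m, g$superset, g$grouping, names(vals), sep = ".")
    pieces[[length(pieces) + 1L]] <- tibble::as_tibble(vals)
  }
  out <- dplyr::bind_cols(pieces)
  if (m != "wave") {
    cv <- covariance_features(recording, catalog, act)
    names(cv) <- paste(m, names(cv), sep = ".")
    out <- dplyr::bind_cols(out, cv)
  }

  imputed <- names(out)[vapply(out, is.na, TRUE)]
  if (length(imputed)) {
    for (nm in imputed) {
      out[[nm]] <- if (grepl("\\.t_activ$", nm)) 1 else 0
    }
    if (!quiet) {
      rlang::inform(paste0(
        "Imputed undefined feature(s) for ", recording$subject_id, " (", m,
        "): ", paste(imputed, collapse = ", ")
      ))
    }
  }
  attr(out, "imputed") <- imputed
  out
}

#' Extract feature tables for a whole cohort
#'
#' Filters every recording per sensor (zero-phase low-pass Butterworth) and
#' assembles one feature table per maneuver: subjects in rows, named
#' features in columns, with `subject_id` and `label` leading.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param catalog A `pf_catalog`.
#' @param act An [activation_config()].
#' @param cutoff,order Filter parameters, see [zero_lag_lowpass()].
#' @return Named list of per-maneuver feature tibbles.
#' @export
extract_cohort_features <- function(cohort, catalog = build_superset_catalog(),
                                    act = activation_config(),
                                    cutoff = 8, order = 8) {
  split_m <- split(cohort, factor(cohort$maneuver, levels = maneuver_ids()))
  purrr::map(split_m, function(df) {
    feats <- purrr::map(df$recording, function(rec) {
      extract_maneuver_features(
        filter_recording(rec, cutoff = cutoff, order = order),
        catalog, act
      )
    })
    dplyr::bind_cols(
      tibble::tibble(subject_id = df$subject_id, label = df$label),
      dplyr::bind_rows(feats)
    )
  })
}

#' Feature table column helpers and CSV round trip
#'
#' A feature table is a tibble whose first columns are `subject_id` and
#' `label`, followed by numeric feature columns with unique names.
#'
#' @param table A feature table.
#' @return `feature_names()`: character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "label"))
}

#' @rdname feature_names
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname feature_names
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double()
  ))
}
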