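#' Sensor matrix geometry configuration
#'
#' Describes how the 10 x 10 sensor matrix maps onto anatomy. Columns run
#' around the probe circumference and are grouped into four quadrants
#' (posterior, anterior, right, left); rows (rings) run along the probe axis
#' and are grouped into three bands (cranial, medial, caudal) of 3/4/3 rows.
#' Only the anterior columns (8 and 9) are anchored by the insertion
#' protocol; the remaining quadrant memberships and the axial orientation are
#' configurable.
#'
#' @param quadrant_map Named list mapping quadrant name to its column
#'   indices; must cover all columns exactly once.
#' @param lat_bands Named list mapping band name (`cranial`, `medial`,
#'   `caudal`) to row indices, sizes 3/4/3, covering all rows.
#' @param row1_position Whether row 1 of the array is at the deep (cranial)
#'   end or the vaginal-opening end. With `"opening_end"` the band-to-row
#'   assignment is mirrored.
#' @return A `pf_geometry_config` list.
#' @export
geometry_config <- function(
    quadrant_map = list(
      posterior = c(3L, 4L),
      anterior = c(8L, 9L),
      right = c(5L, 6L, 7L),
      left = c(10L, 1L, 2L)
    ),
    lat_bands = list(cranial = 1:3, medial = 4:7, caudal = 8:10),
    row1_position = c("deep_end", "opening_end")) {
  row1_position <- match.arg(row1_position)
  n_rows <- 10L
  n_cols <- 10L

  cols <- sort(unlist(quadrant_map, use.names = FALSE))
  if (!identical(as.integer(cols), seq_len(n_cols))) {
    bad <- setdiff(seq_len(n_cols), cols)
    dup <- unique(cols[duplicated(cols)])
    rlang::abort(paste0(
      "`quadrant_map` must assign each of the 10 columns to exactly one ",
      "quadrant",
      if (length(bad)) paste0("; missing column(s): ",
                              paste(bad, collapse = ", ")) else "",
      if (length(dup)) paste0("; duplicated column(s): ",
                              paste(dup, collapse = ", ")) else ""
    ))
  }
  if (!setequal(names(lat_bands), c("cranial", "medial", "caudal"))) {
    rlang::abort("`lat_bands` must name bands cranial, medial, caudal.")
  }
  sizes <- vapply(lat_bands[c("cranial", "medial", "caudal")], length, 1L)
  rows <- sort(unlist(lat_bands, use.names = FALSE))
  if (!identical(as.integer(rows), seq_len(n_rows)) ||
      !identical(unname(sizes), c(3L, 4L, 3L))) {
    rlang::abort(paste0(
      "`lat_bands` must cover all 10 rows with band sizes 3/4/3; got sizes ",
      paste(sizes, collapse = "/"), "."
    ))
  }
  if (row1_position == "opening_end") {
    lat_bands <- lapply(lat_bands, function(r) sort(n_rows + 1L - r))
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         quadrant_map = lapply(quadrant_map, as.integer),
         lat_bands = lapply(lat_bands, as.integer),
         row1_position = row1_position),
    class = "pf_geometry_config"
  )
}

grouping_members <- function(rows, cols) {
  g <- expand.grid(row = as.integer(rows), col = as.integer(cols))
  as.matrix(g[order(g$col, g$row), , drop = FALSE])
}

#' Build the six sensor-grouping supersets
#'
#' Constructs the families of sensor sets over which features are computed:
#' * `s_long`: the four quadrants (posterior, anterior, right, left);
#' * `s_lat`: the three axial bands (cranial, medial, caudal);
#' * `planes`: five 20-sensor planes, plane *i* = columns *i* and *i + 5*
#'   (two diametrically opposed sensor lines);
#' * `rings`: ten 10-sensor circumferential rows;
#' * `s_long_x_s_lat`: the twelve quadrant-by-band intersections;
#' * `whole_matrix`: all 100 sensors.
#'
#' @param config A [geometry_config()].
#' @return A `pf_catalog`: named list of supersets, each a named list of
#'   integer member matrices with columns `row`, `col`.
#' @export
build_superset_catalog <- function(config = geometry_config()) {
  stopifnot(inherits(config, "pf_geometry_config"))
  all_rows <- seq_len(config$n_rows)
  all_cols <- seq_len(config$n_cols)

  s_long <- lapply(config$quadrant_map, function(cc) {
    grouping_members(all_rows, cc)
  })
  s_lat <- lapply(config$lat_bands, function(rr) {
    grouping_members(rr, all_cols)
  })
  planes <- stats::setNames(
    lapply(1:5, function(i) grouping_members(all_rows, c(i, i + 5L))),
    paste0("plane_", 1:5)
  )
  rings <- stats::setNames(
    lapply(all_rows, function(j) grouping_members(j, all_cols)),
    sprintf("ring_%02d", all_rows)
  )
  inter <- list()
  for (q in names(config$quadrant_map)) {
    for (b in c("cranial", "medial", "caudal")) {
      inter[[paste(q, b, sep = "_")]] <-
        grouping_members(config$lat_bands[[b]], config$quadrant_map[[q]])
    }
  }
  whole <- list(whole = grouping_members(all_rows, all_cols))

  structure(
    list(s_long = s_long, s_lat = s_lat, planes = planes, rings = rings,
         s_long_x_s_lat = inter, whole_matrix = whole),
    class = "pf_catalog", config = config
  )
}

#' Flatten a superset catalog
#'
#' @param catalog A `pf_catalog`.
#' @return A tibble with one row per grouping: `superset`, `grouping`,
#'   `n_members` and a `members` list-column of (row, col) matrices.
#' @export
catalog_groupings <- function(catalog) {
  stopifnot(inherits(catalog, "pf_catalog"))
  purrr::map_dfr(names(catalog), function(ss) {
    tibble::tibble(
      superset = ss,
      grouping = names(catalog[[ss]]),
      n_members = vapply(catalog[[ss]], nrow, 1L),
      members = unname(catalog[[ss]])
    )
  })
}

#' Export / import a superset catalog as JSON
#'
#' Groupings are stored as `superset -> grouping -> list of [row, col]`
#' 1-based index pairs.
#'
#' @param catalog A `pf_catalog`.
#' @param path JSON file path.
#' @return `path` invisibly for the writer; a `pf_catalog` for the reader.
#' @export
catalog_to_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "pf_catalog"))
  obj <- lapply(catalog, function(ss) {
    lapply(ss, function(m) unname(apply(m, 1, as.integer, simplify = FALSE)))
  })
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname catalog_to_json
#' @export
catalog_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cat_list <- lapply(obj, function(ss) {
    lapply(ss, function(g) {
      m <- do.call(rbind, lapply(g, function(p) as.integer(unlist(p))))
      colnames(m) <- c("row", "col")
      m
    })
  })
  structure(cat_list, class = "pf_catalog")
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward pass of a Butterworth design of half the requested
#' order, giving the requested effective attenuation order with zero phase
#' lag. Startup transients are controlled by odd-reflection padding of three
#' times the effective order at both ends.
#'
#' @param x Uniformly sampled numeric series.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cut-off frequency (Hz); must satisfy `fs > 2 * cutoff`.
#' @param order Effective filter order (even; the designed base filter has
#'   order `order / 2` and is applied twice).
#' @return Filtered series, same length as `x`.
#' @export
zero_lag_lowpass <- function(x, fs, cutoff = 8, order = 8) {
  if (order %% 2 != 0 || order < 2) {
    rlang::abort("`order` must be a positive even integer.")
  }
  if (fs <= 2 * cutoff) {
    rlang::abort("`fs` must exceed twice the cut-off frequency.")
  }
  n <- length(x)
  pad <- 3L * order
  if (n <= pad) {
    rlang::abort(sprintf(
      "Series of length %d is too short for reflection padding (%d samples).",
      n, pad
    ))
  }
  bf <- signal::butter(order / 2, cutoff / (fs / 2), type = "low")
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  # reference each pass to its starting value so the zero-state startup
  # transient vanishes (a constant series passes through exactly)
  run <- function(v) {
    v0 <- v[1]
    as.numeric(signal::filter(bf, v - v0)) + v0
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[pad + seq_len(n)]
}

#' Filter every sensor of a recording
#'
#' Applies [zero_lag_lowpass()] to each of the 100 sensor time series.
#' Filtering precedes any grouping or feature extraction.
#'
#' @param recording A `pf_recording`.
#' @inheritParams zero_lag_lowpass
#' @return The recording with filtered `values` and `filtered = TRUE`.
#' @export
filter_recording <- function(recording, cutoff = 8, order = 8) {
  stopifnot(inherits(recording, "pf_recording"))
  d <- dim(recording$values)
  mat <- matrix(recording$values, nrow = d[1])
  mat <- apply(mat, 2, zero_lag_lowpass, fs = recording$fs,
               cutoff = cutoff, order = order)
  recording$values <- array(mat, dim = d)
  recording$filtered <- TRUE
  recording
}

#' Peak and sum time series of a sensor grouping
#'
#' For a sensor set S, the peak series is the per-frame maximum over member
#' sensors and the sum series is the per-frame sum.
#'
#' @param recording A `pf_recording` (already filtered per sensor).
#' @param members Integer matrix of grouping members with columns
#'   `row`, `col`, or a single grouping taken from a `pf_catalog`.
#' @param grouping_name Name carried into the result.
#' @return A `pf_series`: list with `y_peak`, `y_sum` (kPa), `fs`,
#'   `grouping_name`, `n_members`, `baseline_s` and `maneuver`.
#' @export
grouping_series <- function(recording, members, grouping_name = "grouping") {
  stopifnot(inherits(recording, "pf_recording"))
  members <- as.matrix(members)
  if (nrow(members) == 0) rlang::abort("Grouping has no members.")
  d <- dim(recording$values)
  if (any(members[, 1] < 1 | members[, 1] > d[2] |
          members[, 2] < 1 | members[, 2] > d[3])) {
    rlang::abort("Grouping member indices fall outside the sensor grid.")
  }
  mat <- matrix(recording$values, nrow = d[1])
  idx <- (members[, 2] - 1L) * d[2] + members[, 1]
  sub <- mat[, idx, drop = FALSE]
  structure(
    list(
      y_peak = do.call(pmax, as.data.frame(sub)),
      y_sum = rowSums(sub),
      fs = recording$fs,
      grouping_name = grouping_name,
      n_members = nrow(members),
      baseline_s = recording$baseline_s,
      maneuver = recording$maneuver
    ),
    class = "pf_series"
  )
}
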