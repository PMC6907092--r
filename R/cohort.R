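#' Maneuver catalogue
#'
#' The four instructed pelvic floor tasks and their execution durations in
#' seconds: 3 s maximal squeeze, 5 s Valsalva push, 10 s sustained hold and a
#' 4 s caudal-cranial contraction / cranial-caudal relaxation wave.
#'
#' @return Named numeric vector of maneuver durations (seconds).
#' @export
maneuver_durations <- function() {
  c(max_contraction = 3, valsalva = 5, endurance = 10, wave = 4)
}

maneuver_ids <- function() names(maneuver_durations())

assert_maneuver <- function(maneuver) {
  if (!is.character(maneuver) || length(maneuver) != 1L ||
      !maneuver %in% maneuver_ids()) {
    rlang::abort(paste0(
      "Unknown maneuver ", deparse(maneuver), "; expected one of: ",
      paste(maneuver_ids(), collapse = ", ")
    ))
  }
  maneuver
}

#' Between-class effect on the synthetic cohort
#'
#' Describes how recordings of the incontinent class differ, in distribution,
#' from the continent class. All effects act on the incontinent group only;
#' the neutral setting (`1, 0, 0, 0, 0`) makes the two classes exchangeable.
#'
#' @param amplitude_ratio Multiplicative factor on contraction amplitude for
#'   the incontinent class (`1` = no difference, `< 1` = weaker contraction).
#' @param timing_shift_frac Shift of the activation peak, as a fraction of the
#'   maneuver duration (positive = delayed response).
#' @param plateau_decay Exponential decay rate of the endurance plateau
#'   (unitless, over the plateau span; `0` = perfectly sustained hold).
#' @param wave_asymmetry Imbalance between contraction and relaxation phase
#'   durations of the wave maneuver (fraction of the maneuver; positive =
#'   slower contraction, faster relaxation).
#' @param spatial_focus_shift Displacement, in ring indices, of the
#'   high-pressure zone along the probe axis.
#' @return A `pf_class_effect` list.
#' @export
class_effect <- function(amplitude_ratio = 1, timing_shift_frac = 0,
                         plateau_decay = 0, wave_asymmetry = 0,
                         spatial_focus_shift = 0) {
  vals <- c(amplitude_ratio, timing_shift_frac, plateau_decay,
            wave_asymmetry, spatial_focus_shift)
  if (!all(is.finite(vals))) {
    rlang::abort("All class-effect fields must be finite numbers.")
  }
  if (amplitude_ratio <= 0) {
    rlang::abort("`amplitude_ratio` must be > 0.")
  }
  structure(
    list(
      amplitude_ratio = amplitude_ratio,
      timing_shift_frac = timing_shift_frac,
      plateau_decay = plateau_decay,
      wave_asymmetry = wave_asymmetry,
      spatial_focus_shift = spatial_focus_shift
    ),
    class = "pf_class_effect"
  )
}

#' Default planted class effect
#'
#' Moderate group differences used as the package's reference synthetic study
#' conditions: a weaker (75%) contraction amplitude, a 10% delayed peak, a
#' decaying endurance plateau, a slower wave contraction phase and a one-ring
#' caudal shift of the pressure focus in the incontinent class.
#'
#' @return A `pf_class_effect`.
#' @export
default_class_effect <- function() {
  class_effect(
    amplitude_ratio = 0.75,
    timing_shift_frac = 0.10,
    plateau_decay = 1.5,
    wave_asymmetry = 0.20,
    spatial_focus_shift = 1
  )
}

neutral_effect <- function() class_effect()

#' Synthetic cohort configuration
#'
#' Parameters of the seeded generator emulating the acquisition protocol:
#' a 10 x 10 capacitive matrix sampled at 50 Hz, 0.42 kPa resolution and a
#' 0.50-100.00 kPa measurement range, with a 1 s pre-command rest segment
#' prepended to every maneuver.
#'
#' @param n_per_class Subjects per class (continent / incontinent).
#' @param seed Master seed; per-subject streams are derived from it by a
#'   counter-based split, so generation is order-independent.
#' @param fs Sampling rate in Hz.
#' @param baseline_kpa Mean and SD (kPa) of the subject-level resting pressure.
#' @param amplitude_kpa Mean and SD (kPa) of the subject-level contraction
#'   amplitude (before any class effect).
#' @param noise_sd_kpa SD of i.i.d. Gaussian sensor noise per frame, applied
#'   before quantization.
#' @param quantization_kpa Sensor resolution step; stored pressures are
#'   multiples of it (0 disables quantization).
#' @param clip_range_kpa Measurement range `(min, max)` in kPa; values are
#'   clamped to the nearest quantization level inside this range.
#' @param baseline_s Duration of the pre-command rest segment (seconds).
#' @param timing_jitter_sd Per-recording SD of the peak-timing jitter
#'   (fraction of maneuver duration), common to both classes.
#' @param effect A [class_effect()] describing the incontinent class.
#' @return A `pf_cohort_config` list.
#' @export
cohort_config <- function(n_per_class = 24, seed = 1, fs = 50,
                          baseline_kpa = c(mean = 5, sd = 1),
                          amplitude_kpa = c(mean = 20, sd = 4),
                          noise_sd_kpa = 0.8,
                          quantization_kpa = 0.42,
                          clip_range_kpa = c(0.50, 100.00),
                          baseline_s = 1,
                          timing_jitter_sd = 0.03,
                          effect = default_class_effect()) {
  if (n_per_class < 1) rlang::abort("`n_per_class` must be >= 1.")
  if (fs <= 0) rlang::abort("`fs` must be > 0.")
  if (length(clip_range_kpa) != 2 || clip_range_kpa[1] >= clip_range_kpa[2]) {
    rlang::abort("`clip_range_kpa` must be (min, max) with min < max.")
  }
  if (quantization_kpa < 0) rlang::abort("`quantization_kpa` must be >= 0.")
  if (noise_sd_kpa < 0) rlang::abort("`noise_sd_kpa` must be >= 0.")
  if (baseline_s < 0) rlang::abort("`baseline_s` must be >= 0.")
  stopifnot(inherits(effect, "pf_class_effect"))
  structure(
    list(
      n_per_class = as.integer(n_per_class), seed = as.integer(seed), fs = fs,
      baseline_kpa = c(mean = unname(baseline_kpa[1]),
                       sd = unname(baseline_kpa[2])),
      amplitude_kpa = c(mean = unname(amplitude_kpa[1]),
                        sd = unname(amplitude_kpa[2])),
      noise_sd_kpa = noise_sd_kpa,
      quantization_kpa = quantization_kpa,
      clip_range_kpa = unname(clip_range_kpa),
      baseline_s = baseline_s,
      timing_jitter_sd = timing_jitter_sd,
      effect = effect
    ),
    class = "pf_cohort_config"
  )
}

raised_cosine <- function(u) 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Maneuver activation envelope
#'
#' Smooth, closed-form activation profile of each maneuver on normalized time
#' `[0, 1]`, built from raised-cosine ramps. The maximal contraction and
#' Valsalva envelopes peak near mid-maneuver (shifted by
#' `timing_shift_frac`); the endurance envelope ramps up, holds a plateau
#' that decays at rate `plateau_decay`, and ramps down; the wave envelope is
#' the temporal amplitude of a traveling activation whose spatial center is
#' given by [wave_ring_center()].
#'
#' @param maneuver One of `"max_contraction"`, `"valsalva"`, `"endurance"`,
#'   `"wave"`.
#' @param t_norm Normalized time in `[0, 1]` (vectorized).
#' @param effect A [class_effect()]; the neutral effect gives the continent
#'   class profile.
#' @param timing_jitter Extra peak-time shift (fraction of the maneuver),
#'   used by the generator for per-recording variability.
#' @return Unitless activation values in `[0, 1]`, 0 at `t_norm = 0`.
#' @export
maneuver_envelope <- function(maneuver, t_norm, effect = class_effect(),
                              timing_jitter = 0) {
  assert_maneuver(maneuver)
  if (any(t_norm < 0 | t_norm > 1)) {
    rlang::abort("`t_norm` must lie in [0, 1].")
  }
  shift <- effect$timing_shift_frac + timing_jitter
  switch(maneuver,
    max_contraction = {
      tp <- clamp(0.5 + shift, 0.05, 0.95)
      ifelse(t_norm <= tp,
             raised_cosine(t_norm / tp),
             raised_cosine((1 - t_norm) / (1 - tp)))
    },
    valsalva = {
      t1 <- clamp(0.25 + shift, 0.05, 0.45)
      t2 <- t1 + 0.5
      out <- rep(1, length(t_norm))
      up <- t_norm < t1
      dn <- t_norm > t2
      out[up] <- raised_cosine(t_norm[up] / t1)
      out[dn] <- raised_cosine((1 - t_norm[dn]) / (1 - t2))
      out
    },
    endurance = {
      t1 <- 0.1
      t2 <- 0.9
      d <- max(effect$plateau_decay, 0)
      out <- exp(-d * (clamp(t_norm, t1, t2) - t1) / (t2 - t1))
      up <- t_norm < t1
      dn <- t_norm > t2
      out[up] <- raised_cosine(t_norm[up] / t1)
      out[dn] <- out[dn] * raised_cosine((1 - t_norm[dn]) / (1 - t2))
      out
    },
    wave = {
      tp <- clamp(0.5 + effect$wave_asymmetry + timing_jitter, 0.1, 0.9)
      ifelse(t_norm <= tp,
             raised_cosine(t_norm / tp),
             raised_cosine((1 - t_norm) / (1 - tp)))
    }
  )
}

#' Spatial center of the traveling wave activation
#'
#' During the wave maneuver the contraction front travels caudal to cranial
#' and back: the ring index of maximal activation moves from the caudal end
#' (ring 9) up to the cranial end (ring 2) by the turning point of the
#' envelope, then returns.
#'
#' @inheritParams maneuver_envelope
#' @return Ring index (possibly fractional) of the activation center.
#' @export
wave_ring_center <- function(t_norm, effect = class_effect(),
                             timing_jitter = 0) {
  tp <- clamp(0.5 + effect$wave_asymmetry + timing_jitter, 0.1, 0.9)
  frac <- ifelse(t_norm <= tp, t_norm / tp, (1 - t_norm) / (1 - tp))
  9 - 7 * frac + effect$spatial_focus_shift
}

# Static spatial weight map: separable Gaussian ring profile (bump on the
# high-pressure zone around ring 3.5, shifted along the probe by the class
# effect) times a mild posterior-dominant column profile. Normalized to max 1.
spatial_weight_map <- function(effect = class_effect(), n_rows = 10,
                               n_cols = 10, ring_sd = 2) {
  ring_w <- exp(-((seq_len(n_rows) - (3.5 + effect$spatial_focus_shift))^2) /
                  (2 * ring_sd^2))
  col_w <- 1 + 0.25 * cos(2 * pi * (seq_len(n_cols) - 3.5) / n_cols)
  map <- outer(ring_w, col_w)
  map / max(map)
}

quantize_clip <- function(x, q, clip) {
  if (q > 0) {
    x <- round(x / q) * q
    lo <- ceiling(clip[1] / q) * q
    hi <- floor(clip[2] / q) * q
  } else {
    lo <- clip[1]
    hi <- clip[2]
  }
  pmin(pmax(x, lo), hi)
}

# Counter-based per-subject stream seed: order-independent reproducibility.
subject_stream_seed <- function(seed, index) {
  s <- ((as.numeric(seed) %% 65011) + 1) * 32749 + 7919 * as.numeric(index)
  as.integer(s %% 2147483647)
}

#' Generate one synthetic pressure recording
#'
#' Builds `baseline + amplitude * envelope * spatial map + noise`, then
#' quantizes to the sensor resolution and clamps to the measurement range.
#' Class differences enter through [class_effect()]; continent subjects use
#' the neutral effect.
#'
#' @param config A [cohort_config()].
#' @param subject_id Subject identifier string.
#' @param label `"continent"` or `"incontinent"`.
#' @param maneuver Maneuver id (see [maneuver_durations()]).
#' @param stream_seed Optional integer seed for this recording's random
#'   stream; when `NULL` the current RNG state is used.
#' @return A `pf_recording`: list with `values` (time x 10 x 10 array, kPa),
#'   `fs`, `maneuver`, `subject_id`, `label`, `baseline_s` and a `filtered`
#'   flag.
#' @export
generate_recording <- function(config, subject_id, label, maneuver,
                               stream_seed = NULL) {
  stopifnot(inherits(config, "pf_cohort_config"))
  assert_maneuver(maneuver)
  label <- match.arg(label, c("continent", "incontinent"))
  if (!is.null(stream_seed)) set.seed(as.integer(stream_seed))
  eff <- if (label == "incontinent") config$effect else neutral_effect()

  duration <- maneuver_durations()[[maneuver]]
  fs <- config$fs
  n_base <- round(config$baseline_s * fs)
  n_act <- round(duration * fs)
  n_t <- n_base + n_act
  n_rows <- 10L
  n_cols <- 10L

  baseline <- stats::rnorm(1, config$baseline_kpa["mean"],
                           config$baseline_kpa["sd"])
  amplitude <- max(stats::rnorm(1, config$amplitude_kpa["mean"],
                                config$amplitude_kpa["sd"]), 0)
  jitter <- stats::rnorm(1, 0, config$timing_jitter_sd)
  amplitude <- amplitude * eff$amplitude_ratio

  t_norm <- if (n_act > 1) (seq_len(n_act) - 1) / (n_act - 1) else 0
  env <- maneuver_envelope(maneuver, t_norm, eff, timing_jitter = jitter)

  act <- array(0, dim = c(n_t, n_rows, n_cols))
  if (maneuver == "wave") {
    # traveling activation: time-varying Gaussian ring profile x column profile
    center <- wave_ring_center(t_norm, eff, timing_jitter = jitter)
    ring_w <- exp(-(outer(center, seq_len(n_rows), "-")^2) / (2 * 2^2))
    col_w <- 1 + 0.25 * cos(2 * pi * (seq_len(n_cols) - 3.5) / n_cols)
    col_w <- col_w / max(col_w)
    tr <- outer(env, rep(1, n_rows)) * ring_w        # n_act x n_rows
    for (ci in seq_len(n_cols)) {
      act[n_base + seq_len(n_act), , ci] <- amplitude * tr * col_w[ci]
    }
  } else {
    map <- spatial_weight_map(eff, n_rows, n_cols)
    for (ci in seq_len(n_cols)) {
      act[n_base + seq_len(n_act), , ci] <-
        amplitude * outer(env, map[, ci])
    }
  }

  values <- baseline + act
  if (config$noise_sd_kpa > 0) {
    values <- values + stats::rnorm(length(values), 0, config$noise_sd_kpa)
  }
  values <- quantize_clip(values, config$quantization_kpa,
                          config$clip_range_kpa)
  dim(values) <- c(n_t, n_rows, n_cols)

  structure(
    list(values = values, fs = fs, maneuver = maneuver,
         subject_id = subject_id, label = label,
         baseline_s = config$baseline_s, filtered = FALSE),
    class = "pf_recording"
  )
}

#' @exportS3Method base::print
print.pf_recording <- function(x, ...) {
  cat(sprintf(
    "<pf_recording> %s | %s | %s | %d frames @ %g Hz (%.1f s rest)%s\n",
    x$subject_id, x$label, x$maneuver, dim(x$values)[1], x$fs, x$baseline_s,
    if (x$filtered) " [filtered]" else ""
  ))
  invisible(x)
}

#' Generate a balanced synthetic cohort
#'
#' Produces `2 * n_per_class` subjects, each recorded over the four
#' maneuvers. Each subject owns an RNG stream derived from the master seed by
#' a counter-based split, so the cohort is a pure function of the
#' configuration and is independent of generation order.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject x maneuver: `subject_id`,
#'   `label`, `maneuver` and a `recording` list-column of `pf_recording`s.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "pf_cohort_config"))
  n <- config$n_per_class
  subjects <- tibble::tibble(
    subject_id = c(sprintf("C%02d", seq_len(n)), sprintf("I%02d", seq_len(n))),
    label = rep(c("continent", "incontinent"), each = n),
    .index = seq_len(2 * n)
  )
  rows <- purrr::pmap(subjects, function(subject_id, label, .index) {
    set.seed(subject_stream_seed(config$seed, .index))
    recs <- purrr::map(maneuver_ids(), function(m) {
      generate_recording(config, subject_id, label, m)
    })
    tibble::tibble(
      subject_id = subject_id, label = label,
      maneuver = maneuver_ids(), recording = recs
    )
  })
  dplyr::bind_rows(rows)
}

#' Cohort label table
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return A tibble `subject_id`, `label`, one row per subject.
#' @export
cohort_labels <- function(cohort) {
  dplyr::distinct(cohort, .data$subject_id, .data$label)
}

#' Export a recording to long-format CSV
#'
#' Writes one row per (frame, row, column) with the pressure in kPa.
#'
#' @param recording A `pf_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "pf_recording"))
  d <- dim(recording$values)
  long <- tidyr::expand_grid(
    t = seq_len(d[1]), row = seq_len(d[2]), col = seq_len(d[3])
  )
  long$kpa <- recording$values[cbind(long$t, long$row, long$col)]
  readr::write_csv(long, path)
  invisible(path)
}
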