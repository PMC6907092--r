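# Independent brute-force oracles used to check the package's closed-form
# implementations. These deliberately use naive loops / direct formula
# transcriptions and never call the code paths they verify.

# Build a pf_series-like object directly from peak/sum vectors.
toy_series <- function(y_peak, y_sum = 2 * y_peak, fs = 1, baseline_s = 0,
                       maneuver = "endurance") {
  structure(
    list(y_peak = y_peak, y_sum = y_sum, fs = fs, grouping_name = "toy",
         n_members = 2L, baseline_s = baseline_s, maneuver = maneuver),
    class = "pf_series"
  )
}

# Naive evaluation of the extremum/instant formulas on a series split into a
# baseline of n_base samples and a maneuver window.
naive_extremum <- function(yp, ys, n_base, mult = 2, use_mean = TRUE) {
  w <- yp[(n_base + 1):length(yp)]
  ws <- ys[(n_base + 1):length(ys)]
  nw <- length(w)
  tn <- function(i) if (nw > 1) (i - 1) / (nw - 1) else 0
  ip <- which(w == max(w))[1]  # earliest index attaining the maximum
  is <- which(ws == max(ws))[1]
  base <- yp[seq_len(n_base)]
  delta <- mult * stats::sd(base)
  if (use_mean) delta <- delta + mean(base)
  ia <- NA_integer_
  for (i in seq_len(nw)) {
    if (!is.na(delta) && w[i] > delta) { ia <- i; break }
  }
  list(max_p = max(w), max_s = max(ws), t_max_p = tn(ip), t_max_s = tn(is),
       t_activ = if (is.na(ia)) NA_real_ else tn(ia))
}

naive_integrals <- function(yp, ys, n_base) {
  w <- (n_base + 1):length(yp)
  list(int_p = sum(yp[w]), int_s = sum(ys[w]))
}

naive_plateau <- function(yp, n_base, fs) {
  w <- yp[(n_base + 1):length(yp)]
  thr <- 0.9 * max(w)
  best <- 0L
  run <- 0L
  for (v in w) {
    if (v >= thr) {
      run <- run + 1L
      if (run > best) best <- run
    } else {
      run <- 0L
    }
  }
  best / fs
}

naive_wave_rates <- function(yp, n_base) {
  w <- yp[(n_base + 1):length(yp)]
  nw <- length(w)
  i <- which(w == max(w))[1]
  tm <- (i - 1) / (nw - 1)
  list(
    cr = if (tm > 0) (max(w) - w[1]) / tm else NA_real_,
    rr = if (tm < 1) (w[nw] - max(w)) / (1 - tm) else NA_real_
  )
}

# Mahalanobis criterion recomputed directly from the definition (R solve on
# the explicitly assembled pooled covariance).
oracle_criterion <- function(table, subset, ridge = 0) {
  x <- as.matrix(table[subset])
  x1 <- x[table$label == "continent", , drop = FALSE]
  x2 <- x[table$label == "incontinent", , drop = FALSE]
  n1 <- nrow(x1)
  n2 <- nrow(x2)
  s <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) /
    (n1 + n2 - 2) + diag(ridge, ncol(x))
  d <- colMeans(x1) - colMeans(x2)
  drop(t(d) %*% solve(s, d))
}

# Exhaustive best subset of size d under the oracle criterion.
exhaustive_best_subset <- function(table, d, ridge = 0) {
  fn <- feature_names(table)
  best <- -Inf
  best_sub <- NULL
  for (sub in utils::combn(fn, d, simplify = FALSE)) {
    j <- oracle_criterion(table, sub, ridge)
    if (j > best) {
      best <- j
      best_sub <- sub
    }
  }
  list(criterion = best, selected = sort(best_sub))
}

# Random two-class feature table with optional mean shifts on some features.
random_feature_table <- function(n_per_class = 8, p = 10, shift = NULL,
                                 seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(stats::rnorm(n * p), n, p)
  if (!is.null(shift)) {
    for (j in seq_along(shift)) {
      x[seq_len(n_per_class), j] <- x[seq_len(n_per_class), j] + shift[j]
    }
  }
  colnames(x) <- sprintf("f%02d", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      label = rep(c("continent", "incontinent"), each = n_per_class)
    ),
    tibble::as_tibble(x)
  )
}

# Squared magnitude response of the designed digital Butterworth filter at
# frequency f (Hz), evaluated from its transfer-function coefficients.
filtfilt_gain <- function(f, fs, cutoff, base_order) {
  bf <- signal::butter(base_order, cutoff / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * f / fs)
  h <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(h)^2
}

# Minimal synthetic recording built directly from a values array.
toy_recording <- function(values, fs = 50, maneuver = "max_contraction",
                          baseline_s = 0, filtered = TRUE,
                          label = "continent", subject_id = "T01") {
  structure(
    list(values = values, fs = fs, maneuver = maneuver,
         subject_id = subject_id, label = label, baseline_s = baseline_s,
         filtered = filtered),
    class = "pf_recording"
  )
}
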