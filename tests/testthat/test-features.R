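test_that("extremum features match hand enumeration of a 5-sample series", {
  gs <- toy_series(c(0, 0, 1, 3, 2), baseline_s = 2)
  f <- extremum_features(gs, activation_config(baseline_window_s = 2))
  expect_equal(f$max_p, 3)
  expect_equal(f$max_s, 6)
  expect_equal(f$t_max_p, 0.5)  # window [1, 3, 2]: peak at its midpoint
  expect_equal(f$t_max_s, 0.5)
  expect_equal(f$t_activ, 0)    # baseline SD 0, so the first sample > 0 fires
})

test_that("a constant series leaves the activation instant undefined", {
  gs <- toy_series(rep(4, 10), baseline_s = 3)
  f <- extremum_features(gs, activation_config(baseline_window_s = 3))
  expect_equal(f$max_p, 4)
  expect_equal(f$t_max_p, 0)    # earliest-index tie-break
  expect_true(is.na(f$t_activ))
})

test_that("positive rescaling scales extrema and leaves instants unchanged", {
  set.seed(4)
  yp <- abs(stats::rnorm(20)) + 0.5
  gs1 <- toy_series(yp, 2 * yp, baseline_s = 4)
  gs2 <- toy_series(3 * yp, 6 * yp, baseline_s = 4)
  act <- activation_config(baseline_window_s = 4)
  f1 <- extremum_features(gs1, act)
  f2 <- extremum_features(gs2, act)
  expect_equal(f2$max_p, 3 * f1$max_p)
  expect_equal(f2$max_s, 3 * f1$max_s)
  expect_equal(f2[c("t_max_p", "t_max_s", "t_activ")],
               f1[c("t_max_p", "t_max_s", "t_activ")])
})

test_that("integrals are raw sample sums over the maneuver window", {
  expect_equal(integral_features(toy_series(c(1, 1, 1, 1)))$int_p, 4)
  expect_equal(integral_features(toy_series(c(0, 2, 4)))$int_p, 6)
  gs <- toy_series(c(0, 2, 4))
  f <- integral_features(gs)
  expect_gte(f$int_s, f$int_p)
})

test_that("plateau duration counts the longest 90% run", {
  expect_equal(plateau_duration(toy_series(rep(7, 10), fs = 1)), 10)
  gs <- toy_series(c(0, 10, 10, 9.5, 0, 10), fs = 1)
  expect_equal(plateau_duration(gs), 3)
  expect_equal(plateau_duration(toy_series(5 * c(0, 10, 10, 9.5, 0, 10),
                                           fs = 1)), 3)
})

test_that("wave rates follow their closed forms on ramps and triangles", {
  m <- 6
  ramp <- toy_series(seq(0, m, length.out = 11))
  r <- wave_rates(ramp)
  expect_equal(r$cr, m)
  expect_true(is.na(r$rr))

  tri <- toy_series(c(seq(0, m, length.out = 6), seq(m, 0, length.out = 6)[-1]))
  r <- wave_rates(tri)
  expect_equal(r$cr, 2 * m)
  expect_equal(r$rr, -2 * m)

  set.seed(8)
  y <- c(0, cumsum(abs(stats::rnorm(5))), 3, 1, 0.5)
  fwd <- wave_rates(toy_series(y))
  rev_ <- wave_rates(toy_series(rev(y)))
  expect_equal(abs(fwd$cr), abs(rev_$rr))
  expect_equal(abs(fwd$rr), abs(rev_$cr))
})

test_that("feature formulas agree with brute-force oracles on random series", {
  set.seed(123)
  for (rep_i in 1:100) {
    n_base <- sample(2:4, 1)
    nw <- sample(5:30, 1)
    yp <- round(abs(stats::rnorm(n_base + nw, sd = 3)), 2)
    ys <- yp * stats::runif(1, 1.5, 4) + stats::runif(1, 0, 0.5)
    fs <- sample(c(1, 50), 1)
    gs <- toy_series(yp, ys, fs = fs, baseline_s = n_base / fs)
    act <- activation_config(baseline_window_s = n_base / fs)

    got <- extremum_features(gs, act)
    want <- naive_extremum(yp, ys, n_base)
    expect_equal(got$max_p, want$max_p)
    expect_equal(got$max_s, want$max_s)
    expect_equal(got$t_max_p, want$t_max_p)
    expect_equal(got$t_max_s, want$t_max_s)
    expect_equal(got$t_activ, want$t_activ)

    gi <- integral_features(gs, act)
    wi <- naive_integrals(yp, ys, n_base)
    expect_equal(gi$int_p, wi$int_p)
    expect_equal(gi$int_s, wi$int_s)

    expect_equal(plateau_duration(gs, act), naive_plateau(yp, n_base, fs))

    gw <- wave_rates(gs, act)
    ww <- naive_wave_rates(yp, n_base)
    expect_equal(gw$cr, ww$cr)
    expect_equal(gw$rr, ww$rr)
  }
})

test_that("covariance features reduce to var(z) for identical sum series", {
  ctl <- default_catalog()
  set.seed(2)
  z <- stats::rnorm(40, mean = 10)
  vals <- array(0, dim = c(40, 10, 10))
  for (g in ctl$s_long_x_s_lat) {
    for (r in seq_len(nrow(g))) {
      vals[, g[r, "row"], g[r, "col"]] <- z / nrow(g)
    }
  }
  rec <- toy_recording(vals, maneuver = "valsalva")
  f <- covariance_features(rec, ctl)
  expect_length(f, 23)
  expect_true(all(abs(unlist(f) - stats::var(z)) < 1e-9))
})

test_that("two-frame covariance features match the n = 2 closed form", {
  ctl <- default_catalog()
  set.seed(3)
  vals <- array(stats::rnorm(2 * 100, mean = 5), dim = c(2, 10, 10))
  rec <- toy_recording(vals, maneuver = "endurance")
  f <- covariance_features(rec, ctl)
  sums <- vapply(ctl$s_long_x_s_lat, function(g) {
    c(sum(vals[cbind(1, g[, "row"], g[, "col"])]),
      sum(vals[cbind(2, g[, "row"], g[, "col"])]))
  }, numeric(2))
  # cov of two two-point series a, b: (a1-ab)(b1-bb) + (a2-ab)(b2-bb), n-1 = 1
  cov2 <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b)))
  }
  g1 <- colnames(sums)[1]
  expect_equal(f[[paste0("cov.", g1, ".", g1)]],
               cov2(sums[, 1], sums[, 1]))
  g2 <- colnames(sums)[2]
  expect_equal(f[[paste0("cov.", g2, ".", g1)]],
               cov2(sums[, 2], sums[, 1]))
  expect_error(
    covariance_features(toy_recording(vals, maneuver = "wave"), ctl),
    "wave"
  )
  expect_error(
    covariance_features(toy_recording(vals[1, , , drop = FALSE],
                                      maneuver = "valsalva"), ctl),
    "two time samples"
  )
})

test_that("per-maneuver feature menus have the documented widths and names", {
  feats <- small_cohort_features()
  counts <- feature_menu_counts()
  for (m in names(counts)) {
    expect_length(feature_names(feats[[m]]), counts[[m]])
    expect_false(any(duplicated(names(feats[[m]]))))
    expect_true(all(startsWith(feature_names(feats[[m]]), paste0(m, "."))))
    expect_false(any(is.na(as.matrix(feats[[m]][feature_names(feats[[m]])]))))
  }
})

test_that("extraction is deterministic and refuses unfiltered recordings", {
  rec <- small_cohort()$recording[[1]]
  ctl <- default_catalog()
  expect_error(extract_maneuver_features(rec, ctl), "filtered")
  fr <- filter_recording(rec)
  expect_identical(extract_maneuver_features(fr, ctl),
                   extract_maneuver_features(fr, ctl))
})

test_that("whole-matrix peak features dominate their plane decomposition", {
  rec <- filter_recording(small_cohort()$recording[[5]])
  ctl <- default_catalog()
  f <- extract_maneuver_features(rec, ctl)
  m <- rec$maneuver
  whole <- f[[paste(m, "whole_matrix", "whole", "max_p", sep = ".")]]
  plane_max <- max(vapply(1:5, function(i) {
    f[[paste(m, "planes", paste0("plane_", i), "max_p", sep = ".")]]
  }, numeric(1)))
  expect_equal(whole, plane_max)
})

test_that("feature tables round-trip through CSV losslessly", {
  tbl <- small_cohort_features()$wave
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), tolerance = 1e-12)
})
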