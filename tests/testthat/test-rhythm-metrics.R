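ts_tbl <- function(t, v) tibble::tibble(time_hct = t, value = v)

test_that("LOWESS smoothing reproduces lines and matches the direct oracle", {
  t <- c(0, 3, 7, 11, 16, 21)
  line <- 2 + 0.5 * t
  expect_equal(lowess_smooth(ts_tbl(t, line))$value, line,
               tolerance = 1e-9)
  expect_equal(lowess_smooth(ts_tbl(t, rep(4, 6)))$value, rep(4, 6),
               tolerance = 1e-12)

  withr::with_seed(21, {
    for (n in c(6, 9, 15)) {
      tt <- sort(runif(n, 0, 48))
      vv <- 10 + 4 * cos(2 * pi * (tt - 7) / 24) + rnorm(n, 0, 0.5)
      expect_equal(lowess_smooth(ts_tbl(tt, vv))$value,
                   oracle_lowess(tt, vv, 5), tolerance = 1e-9)
    }
  })
  expect_error(lowess_smooth(ts_tbl(c(1, 2), c(1, 2))),
               class = "chronocope_insufficient_data")
})

test_that("the 24-h sinusoid fit is exact on noiseless data", {
  fit <- fit_sine24(ts_tbl(c(1, 7, 13, 15, 19, 23),
                           c(10, 14, 10, 8, 6, 8)))
  expect_equal(fit$mesor, 10, tolerance = 1e-9)
  expect_equal(fit$amplitude, 4, tolerance = 1e-9)
  expect_equal(fit$acrophase, 7, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  const <- fit_sine24(ts_tbl(c(1, 7, 13, 19), rep(5, 4)))
  expect_equal(const$mesor, 5)
  expect_equal(const$amplitude, 0)
  expect_equal(const$r_squared, 0)

  expect_error(fit_sine24(ts_tbl(c(1, 25, 49, 73), 1:4)),
               class = "chronocope_singular_design")
})

test_that("refitting its own fitted curve reproduces a sine fit", {
  withr::with_seed(5, {
    t <- sort(runif(24, 0, 72))
    v <- 3 + 1.7 * cos(2 * pi * (t - 13) / 24) + rnorm(24, 0, 0.4)  })
  f1 <- fit_sine24(ts_tbl(t, v))
  f2 <- fit_sine24(ts_tbl(t, predict(f1)))
  expect_equal(f2$mesor, f1$mesor, tolerance = 1e-9)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-9)
  expect_equal(f2$acrophase, f1$acrophase, tolerance = 1e-9)
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)
})

test_that("noisy-sinusoid amplitude agrees with a grid-search oracle", {
  withr::with_seed(8, {
    t <- seq(0, 71.5, by = 0.5)
    v <- 10 + 4 * cos(2 * pi * (t - 7) / 24) + rnorm(length(t), 0, 0.5)
  })
  fit <- fit_sine24(ts_tbl(t, v))
  oracle <- oracle_sine_grid(t, v, A_grid = seq(3, 5, by = 0.01),
                             phi_grid = seq(6, 8, by = 0.01))
  expect_lt(abs(fit$amplitude - oracle["A"]), 0.2)
  expect_lt(abs(fit$acrophase - oracle["phi"]), 0.2)
})

test_that("sine fits are shift- and scale-equivariant", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      t <- sort(runif(12, 0, 48))
      v <- 5 + 2 * cos(2 * pi * (t - 3) / 24) + rnorm(12, 0, 0.3)
      f <- fit_sine24(ts_tbl(t, v))
      fs <- fit_sine24(ts_tbl(t, v + 11))
      expect_equal(fs$mesor, f$mesor + 11, tolerance = 1e-9)
      expect_equal(fs$amplitude, f$amplitude, tolerance = 1e-9)
      expect_equal(fs$acrophase, f$acrophase, tolerance = 1e-9)
      k <- 2.5
      fk <- fit_sine24(ts_tbl(t, k * v))
      expect_equal(fk$mesor, k * f$mesor, tolerance = 1e-9)
      expect_equal(fk$amplitude, k * f$amplitude, tolerance = 1e-9)
      expect_equal(compute_auc(ts_tbl(t, k * v)),
                   k * compute_auc(ts_tbl(t, v)), tolerance = 1e-9)
    }
  })
})

test_that("AUC handles rectangles, triangles and the 6-point fixture", {
  expect_equal(compute_auc(ts_tbl(c(0, 24), c(5, 5))), 120)
  t10 <- seq(0, 10, by = 1)
  expect_equal(compute_auc(ts_tbl(t10, t10)), 50, tolerance = 1e-9)

  t <- c(1, 7, 13, 15, 19, 23)
  v <- c(10.2, 13.9, 10.3, 7.8, 6.1, 8.4)
  hand <- oracle_trapz(t, oracle_lowess(t, v, 5))
  expect_equal(compute_auc(ts_tbl(t, v)), hand, tolerance = 1e-9)
  expect_error(compute_auc(ts_tbl(3, 1)),
               class = "chronocope_insufficient_data")
})

test_that("AUC is additive over adjoining windows", {
  withr::with_seed(3, {
    t <- sort(runif(20, 0, 48))
    v <- 4 + cos(2 * pi * t / 24) + rnorm(20, 0, 0.2)
  })
  smoothed <- lowess_smooth(ts_tbl(t, v))
  left <- smoothed[smoothed$time_hct <= 24, ]
  right <- smoothed[smoothed$time_hct >= max(left$time_hct), ]
  expect_equal(compute_auc(left, smooth = FALSE) +
                 compute_auc(right, smooth = FALSE),
               compute_auc(ts_tbl(t, v)), tolerance = 1e-9)
})

test_that("rhythm strength is 1 for a pure 24-h tone and near 0 off-harmonic", {
  t <- seq(0, 71.5, by = 0.5)
  pure <- ts_tbl(t, 3 + 0.8 * cos(2 * pi * (t - 5) / 24))
  expect_equal(rhythm_strength_24h(pure), 1, tolerance = 1e-12)
  # smoothing a pure sinusoid barely changes its strength
  expect_equal(rhythm_strength_24h(lowess_smooth(pure)), 1,
               tolerance = 1e-6)
  # 12-h harmonic is orthogonal on a balanced grid
  half <- ts_tbl(t, 3 + cos(2 * pi * t / 12))
  expect_lt(rhythm_strength_24h(half), 0.05)
  # affine-scaling invariance
  expect_equal(rhythm_strength_24h(ts_tbl(t, 7 + 3 * pure$value)),
               rhythm_strength_24h(pure), tolerance = 1e-12)
  expect_error(rhythm_strength_24h(ts_tbl(t, rep(2, length(t)))),
               class = "chronocope_undefined_strength")
  expect_error(rhythm_strength_24h(ts_tbl(t[t < 40], rnorm(sum(t < 40)))),
               class = "chronocope_insufficient_data")
})

test_that("white-noise rhythm strength matches the regression null expectation", {
  n <- 144
  t <- seq(0, by = 0.5, length.out = n)
  withr::with_seed(42, {
    strengths <- replicate(1000, rhythm_strength_24h(ts_tbl(t, rnorm(n))))
  })
  expect_equal(mean(strengths), 2 / (n - 1), tolerance = 0.15)
})

test_that("Vmax averages the per-day maxima", {
  t <- seq(0, 71, by = 1)
  v <- rep(5, 72)
  v[c(10, 30, 60)] <- c(12, 14, 13)  # one spike per 24-h window
  expect_equal(vmax(ts_tbl(t, v)), 13)
  expect_equal(vmax(ts_tbl(t, rep(7, 72))), 7)

  withr::with_seed(17, { vv <- abs(rnorm(72, 5, 2)) })
  win <- floor(t / 24) + 1
  brute <- mean(tapply(vv, win, max))
  expect_equal(vmax(ts_tbl(t, vv)), brute)
  expect_error(vmax(ts_tbl(t[1:30], vv[1:30])),
               class = "chronocope_insufficient_data")
})

test_that("rhythm_metrics summarises a tidy table per fish and channel", {
  cfg <- test_config(seed = 6, n_groups = 1)
  co <- generate_cohort(cfg)
  ts <- dplyr::bind_rows(
    simulate_channel_timeseries(co, cfg, "cortisol"),
    simulate_activity(co, cfg, n_days_ll = 0))
  m <- rhythm_metrics(ts)
  expect_setequal(unique(m$channel), c("cortisol", "activity"))
  expect_equal(nrow(m), 2 * nrow(co))
  cort <- m[m$channel == "cortisol", ]
  expect_true(all(is.na(cort$rhythm_strength)))  # 6 points, 22-h span
  act <- m[m$channel == "activity", ]
  expect_true(all(act$rhythm_strength >= 0 & act$rhythm_strength <= 1))
  expect_true(all(act$vmax >= apply(cbind(act$mesor), 1, max)))
})
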