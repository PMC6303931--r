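test_that("cohort generation is deterministic, sized and bounded", {
  cfg <- cohort_config(n_groups = 9, group_size = 10, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 90)
  expect_false(anyDuplicated(c1$individual_id) > 0)
  expect_true(all(c1$boldness >= 0 & c1$boldness <= 1))
  expect_error(cohort_config(group_size = 1),
               class = "chronocope_config_error")
})

test_that("adding groups leaves existing fish unchanged", {
  small <- generate_cohort(cohort_config(n_groups = 2, seed = 5))
  big <- generate_cohort(cohort_config(n_groups = 4, seed = 5))
  expect_identical(small, big[big$group_id %in% c("g01", "g02"), ])
})

test_that("body weight is independent of boldness", {
  # Monte-Carlo under independence: mean |rho| stays near its null level
  rhos <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_config(n_groups = 16, group_size = 9,
                                        seed = s))
    cor(co$boldness, co$body_weight_mg, method = "spearman")
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.1)
})

test_that("latency model honours its noise switches", {
  cfg <- cohort_config(n_groups = 1, seed = 3, latency_residual_sd = 0)
  co <- generate_cohort(cfg)
  l1 <- simulate_emergence_latency(co, cfg, "single", "day1")
  l2 <- simulate_emergence_latency(co, cfg, "single", "day2")
  expect_equal(l1$latency_s, l2$latency_s)  # no session noise

  cfg0 <- cohort_config(n_groups = 1, seed = 3, latency_boldness_slope = 0,
                        latency_individual_sd = 0, latency_residual_sd = 0)
  l0 <- simulate_emergence_latency(generate_cohort(cfg0), cfg0)
  expect_true(all(l0$latency_s == cfg0$latency_scale))  # null model
  expect_true(all(l0$latency_s > 0))
})

test_that("test-retest correlation matches a brute-force latency-model oracle", {
  cfg <- cohort_config(n_groups = 16, group_size = 9, seed = 1)
  # package value, averaged over a few cohorts of 144 fish
  rhos <- vapply(1:5, function(s) {
    cfg_s <- cohort_config(n_groups = 16, group_size = 9, seed = s)
    co <- generate_cohort(cfg_s)
    l1 <- simulate_emergence_latency(co, cfg_s, "single", "day1")
    l2 <- simulate_emergence_latency(co, cfg_s, "single", "day2")
    cor(log(l1$latency_s), log(l2$latency_s), method = "spearman")
  }, numeric(1))
  # independent oracle: simulate the shared-signal model directly
  set.seed(99)
  n <- 1e4
  sig <- cfg$latency_boldness_slope * (1 - runif(n)) +
    rnorm(n, 0, cfg$latency_individual_sd)
  o1 <- sig + rnorm(n, 0, cfg$latency_residual_sd)
  o2 <- sig + rnorm(n, 0, cfg$latency_residual_sd)
  oracle <- cor(o1, o2, method = "spearman")
  expect_lt(abs(mean(rhos) - oracle), 0.02)
})

test_that("mirror test produces caps, zero rates and rank-aggression structure", {
  cfg <- cohort_config(n_groups = 1, seed = 2,
                       mirror = mirror_params(frz_scale = 5000))
  co <- generate_cohort(cfg)
  co$boldness[1] <- 0  # shy extreme with freezing parameter at cap
  m <- simulate_mirror_test(co, cfg)
  expect_equal(m$frz_s[1], m$duration_s[1])
  expect_true(all(m$frz_s + m$lfa_s <= m$duration_s + 1e-9))

  cfg0 <- cohort_config(n_groups = 1, seed = 2,
                        mirror = mirror_params(agr_rate_bold = 0,
                                               agr_rate_shy = 0))
  m0 <- simulate_mirror_test(generate_cohort(cfg0), cfg0)
  expect_true(all(m0$agr_count == 0))

  # aggression frequency falls with emergence rank; magnitude vs MC oracle
  pkg_rho <- vapply(1:3, function(s) {
    cfg_s <- cohort_config(n_groups = 9, seed = s)
    co_s <- generate_cohort(cfg_s)
    rk <- rank_emergence(simulate_emergence_latency(co_s, cfg_s),
                         cutoff = Inf)
    sc <- agr_frequency(simulate_mirror_test(co_s, cfg_s))
    j <- merge(rk, sc[!sc$excluded, c("individual_id", "agr_freq")])
    cor(j$rank, j$agr_freq, method = "spearman")
  }, numeric(1))
  mp <- cfg$mirror
  oracle_rho <- local({
    set.seed(7)
    mean(replicate(1000, {
      b <- runif(90)
      g <- rep(1:9, each = 10)
      lat <- 30 * exp(4 * (1 - b) + rnorm(90, 0, 0.1) + rnorm(90, 0, 0.1))
      rk <- ave(lat, g, FUN = rank)
      frz <- pmin(600, 550 * pmax(0, (1 - b) - 0.35) + rexp(90, 1 / 20))
      lfa <- pmin(pmax(0, 600 - frz - 10),
                  5 + 100 * (1 - b) + rexp(90, 1 / 10))
      avail <- 600 - frz - lfa
      rate <- mp$agr_rate_shy + (mp$agr_rate_bold - mp$agr_rate_shy) * b
      f <- rpois(90, rate * avail) / avail
      k <- frz < 600
      cor(rk[k], f[k], method = "spearman")
    }))
  })
  expect_lt(mean(pkg_rho), -0.5)
  expect_lt(abs(mean(pkg_rho) - oracle_rho), 0.1)
})

test_that("channel generator reproduces the cosine arithmetic exactly", {
  cfg <- example_gene_config()
  co <- generate_cohort(cfg)[1, ]
  ts <- simulate_channel_timeseries(co, cfg, "geneX",
                                    timepoints = c(1, 7, 13, 15, 19, 23))
  expect_equal(ts$value, c(10, 14, 10, 8, 6, 8), tolerance = 1e-12)

  # amplitude zero and no noise -> constant mesor
  cfg0 <- cohort_config(n_groups = 1, seed = 1, channel_params = list(
    flat = rhythm_gen_params(7, 7, 0, 0, acrophase = 0, noise_cv = 0)))
  ts0 <- simulate_channel_timeseries(generate_cohort(cfg0)[1, ], cfg0,
                                     "flat")
  expect_true(all(ts0$value == 7))
  expect_error(simulate_channel_timeseries(co, cfg, "nope"),
               class = "chronocope_config_error")
})

test_that("constant light damps the oscillation with the configured half-life", {
  cfg <- cohort_config(n_groups = 1, seed = 1, ll_damping_halflife = 24,
                       channel_params = list(
    geneX = rhythm_gen_params(10, 10, 4, 4, acrophase = 7, noise_cv = 0,
                              floor_at_zero = FALSE)))
  co <- generate_cohort(cfg)[1, ]
  tt <- seq(0, 72, by = 0.5)
  ll <- simulate_channel_timeseries(co, cfg, "geneX", timepoints = tt,
                                    regime = "LL", ll_start = 0)
  # closed-form oracle: evaluate the damped cosine directly and fit day 3
  mu <- 10 + 4 * cos(2 * pi * (tt - 7) / 24) * 2^(-tt / 24)
  expect_equal(ll$value, mu, tolerance = 1e-12)
  day3 <- ll[ll$time_hct >= 48, ]
  amp3 <- fit_sine24(tibble::tibble(time_hct = day3$time_hct,
                                    value = day3$value))$amplitude
  ld <- simulate_channel_timeseries(co, cfg, "geneX",
                                    timepoints = seq(0, 24, by = 0.5))
  amp1 <- fit_sine24(ld[c("time_hct", "value")])$amplitude
  # independent oracle: grid-fit the directly evaluated damped cosine
  t3 <- tt[tt >= 48]
  oracle <- oracle_sine_grid(
    t3, 10 + 4 * cos(2 * pi * (t3 - 7) / 24) * 2^(-t3 / 24),
    A_grid = seq(0.3, 1.3, by = 0.002), phi_grid = seq(5, 9, by = 0.02))
  expect_equal(amp3, unname(oracle["A"]), tolerance = 0.005)
  # the fitted day-3 amplitude sits between the damping bounds 2^-3..2^-2
  expect_gt(amp3 / amp1, 0.125)
  expect_lt(amp3 / amp1, 0.25)
})

test_that("with noise off, rhythm metrics are strictly monotone in boldness", {
  cfg <- noise_free(cohort_config(n_groups = 3, seed = 4))
  co <- generate_cohort(cfg)
  co <- co[order(co$boldness), ]
  for (ch in c("bmal1a", "cipca", "cortisol", "melatonin")) {
    ts <- simulate_channel_timeseries(co, cfg, ch)
    m <- rhythm_metrics(ts)
    m <- m[match(co$individual_id, m$individual_id), ]
    expect_true(all(diff(m$amplitude) > 0), label = paste(ch, "amplitude"))
    if (ch %in% c("cortisol", "melatonin")) {
      expect_true(all(diff(m$mesor) < 0), label = paste(ch, "mesor"))
    } else {
      expect_true(all(diff(m$mesor) > 0), label = paste(ch, "mesor"))
    }
  }
})

test_that("maximum velocity is personality-independent by construction", {
  rhos <- vapply(1:100, function(s) {
    cfg <- cohort_config(n_groups = 3, seed = s)
    co <- generate_cohort(cfg)
    act <- simulate_activity(co, cfg, n_days_ll = 0)
    vm <- vapply(split(act[c("time_hct", "value")], act$individual_id),
                 vmax, numeric(1))
    rk <- rank_emergence(simulate_emergence_latency(co, cfg), cutoff = Inf)
    cor(rk$rank, vm[rk$individual_id], method = "spearman")
  }, numeric(1))
  # mean correlation across cohorts is indistinguishable from zero
  expect_gt(t.test(rhos, mu = 0)$p.value, 0.05)
})
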