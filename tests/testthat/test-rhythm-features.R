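# independent brute-force implementations of the nonparametric statistics
is_oracle <- function(x) {
  N <- length(x); xb <- mean(x)
  hm <- sapply(0:23, function(h) mean(x[(seq_along(x) - 1) %% 24 == h]))
  N * sum((hm - xb)^2) / (24 * sum((x - xb)^2))
}
iv_oracle <- function(x) {
  N <- length(x)
  num <- 0
  for (i in 2:N) num <- num + (x[i] - x[i - 1])^2
  N * num / ((N - 1) * sum((x - mean(x))^2))
}

test_that("IS is 1 for exactly periodic data and 0 for flat hour-of-day means", {
  set.seed(1)
  day <- runif(24)
  expect_equal(interdaily_stability(rep(day, 2)), 1, tolerance = 1e-12)
  # period-48 pattern: every hour-of-day mean is 0.5, total variance positive
  x <- rep(c(rep(0, 24), rep(1, 24)), 2)
  expect_equal(interdaily_stability(x), 0, tolerance = 1e-12)
})

test_that("IS and IV match the direct formulas on random series", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- rexp(120) * 50
    expect_equal(interdaily_stability(x), is_oracle(x), tolerance = 1e-12)
    iv <- intradaily_variability(x)
    expect_equal(as.numeric(iv), iv_oracle(x), tolerance = 1e-12)
  }
})

test_that("IV equals its hand-computed values on canonical inputs", {
  x <- sin(2 * pi * (0:47) / 24)
  expect_equal(as.numeric(intradaily_variability(x)), iv_oracle(x), tolerance = 1e-12)
  expect_equal(as.numeric(intradaily_variability(x)), 0.0667, tolerance = 1e-3)
  alt <- rep(c(0, 1), 24)
  iv <- intradaily_variability(alt)
  expect_equal(as.numeric(iv), 4.0, tolerance = 1e-12)  # 48*47/(47*12)
  expect_true(attr(iv, "out_of_range"))
})

test_that("IV of white noise concentrates near 2", {
  vals <- sapply(1:20, function(s) { set.seed(s); as.numeric(intradaily_variability(rnorm(240))) })
  expect_true(abs(mean(vals) - 2) < 0.1)
  expect_true(all(vals > 1.55 & vals < 2.45))  # ~3.5 sampling SDs at N = 240
})

test_that("degenerate and undersized hourly input is rejected", {
  expect_warning(v <- interdaily_stability(rep(3, 48)), "constant")
  expect_true(is.na(v))
  expect_warning(v2 <- intradaily_variability(rep(3, 48)), "constant")
  expect_true(is.na(v2))
  expect_error(interdaily_stability(rnorm(30)), "48")
  expect_error(interdaily_stability(rnorm(60)), "multiple of 24")
  expect_error(intradaily_variability(rnorm(30)), "48")
})

test_that("IS and IV are invariant to affine count rescaling and rotation", {
  set.seed(4)
  day <- rexp(24) * 30
  x <- rep(day, 5) + rnorm(120, sd = 1)
  x <- pmax(x, 0)
  y <- 3.7 * x + 11
  expect_equal(interdaily_stability(y), interdaily_stability(x), tolerance = 1e-12)
  expect_equal(as.numeric(intradaily_variability(y)),
               as.numeric(intradaily_variability(x)), tolerance = 1e-12)
  # rotating an exactly periodic series permutes the hour-of-day means, so
  # IS is exactly unchanged; IV differs only in one boundary difference
  xp <- rep(day, 5)
  xr <- rep(c(day[6:24], day[1:5]), 5)
  expect_equal(interdaily_stability(xr), interdaily_stability(xp), tolerance = 1e-12)
  expect_equal(as.numeric(intradaily_variability(xr)),
               as.numeric(intradaily_variability(xp)), tolerance = 1e-3)
})

test_that("noise-free extended-cosine parameters are recovered to 1e-3 relative", {
  p <- actigraphy_sim_params(minimum = 10, amplitude = 100, acrophase = 14,
                             alpha = 0.2, beta = 8, dispersion = 0,
                             sleep_duration = 0, days = 7)
  s <- simulate_epoch_actigraphy(p, seed = 1)
  cf <- fit_extended_cosine(s, bin_min = 2)
  expect_equal(cf$status, "full")
  truth <- c(10, 100, 14, 0.2, 8)
  est <- c(cf$minimum, cf$amplitude, cf$acrophase, cf$alpha, cf$beta)
  expect_true(all(abs(est - truth) / truth < 1e-3))
})

test_that("constant series fail cleanly with null shape parameters", {
  s <- epoch_series(rep(40, 2880), 60)
  cf <- fit_extended_cosine(s)
  expect_equal(cf$status, "failed")
  expect_true(is.na(cf$alpha) && is.na(cf$acrophase))
  s2 <- epoch_series(rep(40, 2880), 60, excluded = rep(TRUE, 2880))
  expect_equal(fit_extended_cosine(s2)$status, "failed")
})

test_that("the fitted loss beats a coarse 5-D parameter grid", {
  p <- actigraphy_sim_params(minimum = 20, amplitude = 80, acrophase = 13,
                             alpha = 0.1, beta = 6, dispersion = 5,
                             sleep_duration = 0, days = 2)
  s <- simulate_epoch_actigraphy(p, seed = 99)
  s60 <- downsample_to_60s(s)
  cf <- fit_extended_cosine(s60, bin_min = 1)  # objective = RSS on the 60 s epochs
  t_h <- es_clock_hours(s60); y <- s60$counts
  grid_rss <- Inf
  for (m in c(0, 20, 40)) for (A in c(40, 80, 120))
    for (phi in seq(0, 21, by = 3)) for (al in c(-0.5, 0, 0.5))
      for (be in c(1, 6, 20)) {
        mu <- m + A / (1 + exp(-be * (cos(2 * pi * (t_h - phi) / 24) - al)))
        grid_rss <- min(grid_rss, sum((y - mu)^2))
      }
  expect_lte(cf$rss, grid_rss + 1e-8)
})

test_that("acrophase shifts with the simulated peak and alpha tracks trough width", {
  base <- function(phi, alpha) {
    p <- actigraphy_sim_params(acrophase = phi, alpha = alpha, dispersion = 0,
                               sleep_duration = 0, days = 5)
    fit_extended_cosine(simulate_epoch_actigraphy(p, seed = 1), bin_min = 5)
  }
  f14 <- base(14, 0.2); f17 <- base(17, 0.2)
  expect_equal(circ_diff_h(f17$acrophase, f14$acrophase), 3, tolerance = 0.02)
  f_wide <- base(14, 0.5)  # longer rest fraction
  expect_gt(f_wide$alpha, f14$alpha)
})

test_that("rest-interval summaries use circular midpoints and a floored log SD", {
  iv7 <- data.frame(window = 1:7, duration_h = rep(8, 7), midpoint_h = rep(3, 7))
  rs <- rest_interval_summaries(iv7)
  expect_equal(rs$mean_length_h, 8)
  expect_equal(rs$midpoint_h, 3)
  expect_equal(rs$midpoint_sd_h, 0)
  expect_equal(rs$log_midpoint_sd, log(1 / 120))

  # midnight-straddling pair: circular mean 0:00, sample SD 0.7071 h
  rs2 <- rest_interval_summaries(data.frame(window = 1:2, duration_h = 8,
                                            midpoint_h = c(23.5, 0.5)),
                                 min_intervals = 2)
  expect_lt(abs(circ_diff_h(rs2$midpoint_h, 0)), 1e-10)
  expect_equal(rs2$midpoint_sd_h, sqrt(0.5), tolerance = 1e-10)

  rs3 <- rest_interval_summaries(data.frame(window = 1:3, duration_h = 8,
                                            midpoint_h = c(2, 3, 4)),
                                 min_intervals = 3)
  expect_equal(rs3$midpoint_h, 3, tolerance = 1e-10)
  expect_equal(rs3$midpoint_sd_h, 1, tolerance = 1e-10)
  expect_equal(rs3$log_midpoint_sd, log(1 + 1 / 120), tolerance = 1e-10)
})

test_that("fewer than five intervals yields null sleep features", {
  iv <- data.frame(window = 1:4, duration_h = 8, midpoint_h = 3)
  rs <- rest_interval_summaries(iv)
  expect_true(is.na(rs$mean_length_h) && is.na(rs$midpoint_h))
  expect_equal(rs$n_intervals, 4)
})

test_that("self-report midpoint follows the forward bed-to-wake arc", {
  expect_equal(self_report_midpoint(23, 7), 3)
  expect_equal(self_report_midpoint(1, 9), 5)
  expect_equal(self_report_midpoint(22, 6.5), 2.25)
  expect_true(is.na(self_report_midpoint(8, 8)))
  expect_equal(self_report_midpoint(c(23, 1), c(7, 9)), c(3, 5))
})

test_that("the full session pipeline produces eligible, sane features", {
  s <- simulate_epoch_actigraphy(actigraphy_sim_params(days = 8), seed = 17)
  f <- extract_session_features(s)
  expect_true(f$rar_eligible && f$sleep_eligible)
  expect_true(f$IS > 0.9 && f$IS <= 1)
  expect_true(f$IV >= 0 && f$IV < 0.5)
  expect_lt(abs(circ_diff_h(f$acrophase, 14)), 0.5)
  expect_true(f$alpha > -1 && f$alpha < 1)
  expect_lt(abs(circ_diff_h(f$rest_midpoint_h, 3.5)), 1.5)
})
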