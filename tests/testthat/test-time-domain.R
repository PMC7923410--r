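test_that("constant series segments to constant ANN / HR with full coverage", {
  s <- series_from_nn(rep(1000, 3600))
  seg <- segment_hr(s, 5)
  expect_equal(nrow(seg$segments), 12L)
  expect_equal(seg$segments$ann_ms, rep(1000, 12))
  expect_equal(seg$segments$mean_hr_bpm, rep(60, 12))
  expect_true(all(abs(seg$segments$coverage - 1) < 0.01))
})

test_that("low-coverage windows are dropped and counted", {
  # 2 h record with a 30-min silence in the middle
  nn <- rep(1000, 7200)
  t <- cumsum(nn) / 1000
  keep <- (t <= 2700 | t > 4500) & t < 7200
  s <- beat_series(t[keep], nn[keep])
  seg <- segment_hr(s, 30, min_coverage = 0.5)
  expect_equal(seg$n_dropped, 1L)
  expect_false(any(seg$segments$start_s == 2700))
})

test_that("window means equal a brute-force per-beat grouping", {
  set.seed(3)
  s <- series_from_nn(900 + rnorm(4000, 0, 60))
  seg <- segment_hr(s, 5)
  grp <- split(s$nn, floor(s$t / 300))
  want <- vapply(grp, mean, numeric(1))
  got <- seg$segments$ann_ms
  names(want) <- NULL
  expect_equal(got, want[seq_along(got)], tolerance = 1e-12)
})

test_that("PPG error model reproduces the calibrated table", {
  expect_equal(ppg_noise_sigma(1), 5.91)
  expect_equal(ppg_noise_sigma(5), 5.09)
  expect_equal(ppg_noise_sigma(10), 4.71)
  expect_equal(ppg_noise_sigma(30), 4.01)
  expect_equal(ppg_noise_sigma(60), 3.95)
  expect_equal(ppg_noise_bias(1), 0.03)
  expect_equal(ppg_noise_bias(60), -0.35)
  # log-linear interpolation stays between the bracketing table values
  expect_true(ppg_noise_sigma(20) < 4.71 && ppg_noise_sigma(20) > 4.01)
  expect_error(ppg_noise_sigma(0), "positive")
})

test_that("HR noise injection is the identity at sigma 0 and seed-stable", {
  s <- series_from_nn(rep(850, 4000))
  seg <- segment_hr(s, 1)
  expect_identical(inject_hr_noise(seg, 0, seed = 1), seg)
  n1 <- inject_hr_noise(seg, 5.91, seed = 42)
  n2 <- inject_hr_noise(seg, 5.91, seed = 42)
  expect_identical(n1$segments$mean_hr_bpm, n2$segments$mean_hr_bpm)
  expect_false(identical(n1$segments$mean_hr_bpm,
                         inject_hr_noise(seg, 5.91, seed = 43)$segments$mean_hr_bpm))
})

test_that("injected noise SD converges to the requested sigma", {
  s <- series_from_nn(rep(600, 1000500))  # >1e4 one-minute windows
  seg <- segment_hr(s, 1)
  expect_gte(nrow(seg$segments), 10000L)
  noisy <- inject_hr_noise(seg, 5.91, seed = 7)
  eps <- noisy$segments$mean_hr_bpm - noisy$segments$hr_clean_bpm
  expect_lt(abs(sd(eps) - 5.91) / 5.91, 0.02)
  expect_lt(abs(mean(eps)), 0.2)
})

test_that("SDNN24 follows the population-SD definition", {
  expect_equal(sdnn24(series_from_nn(rep(800, 10))), 0)
  expect_equal(sdnn24(series_from_nn(rep(c(800, 1000), 50))), 100)
  expect_error(sdnn24(series_from_nn(800)), "at least 2")
  # sample-SD option
  x <- c(800, 900, 1000)
  expect_equal(sdnn24(series_from_nn(x), sample = TRUE), sd(x))
})

test_that("SDNNi24 averages per-window SDs (brute-force cross-check)", {
  set.seed(14)
  s <- series_from_nn(850 + rnorm(3999, 0, 50))
  seg <- segment_hr(s, 5)
  pop_sd_ <- function(x) sqrt(mean((x - mean(x))^2))
  grp <- split(s$nn, floor(s$t / 300))
  retained <- as.character(round(seg$segments$start_s / 300))
  want <- mean(vapply(grp[retained], pop_sd_, numeric(1)))
  expect_equal(sdnni24(seg, s), want, tolerance = 1e-9)
  expect_equal(sdnni24(segment_hr(series_from_nn(rep(900, 2000)), 5),
                       series_from_nn(rep(900, 2000))), 0)
})

test_that("SDANN24 is the SD of window means and obeys total variance", {
  # two-window toy: ANN 900 and 1100 -> SDANN 100
  nn <- c(rep(900, 200), rep(1100, 200))
  s <- series_from_nn(nn)
  seg <- segment_hr(s, 3, origin = s$t[1])
  expect_equal(nrow(seg$segments), 2L)
  expect_equal(sdann24(seg), 100, tolerance = 0.5)

  # law of total variance on an exactly equal-count segmentation
  s2 <- equal_count_series()
  seg2 <- segment_hr(s2, 1, origin = s2$t[1])
  expect_true(all(seg2$segments$n_beats == 75L))
  within_var <- vapply(split(s2$nn, floor((s2$t - s2$t[1]) / 60)),
                       function(x) mean((x - mean(x))^2), numeric(1))
  lhs <- sdnn24(s2)^2
  rhs <- mean(within_var) + sdann24(seg2)^2
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("SDANNHR24 equals SDANN24 exactly without noise", {
  g <- generate_beats(generator_profile(seed = 2, ectopic_rate = 0,
                                        gap_rate_per_h = 0, duration_h = 6))
  seg <- segment_hr(g$series, 5)
  expect_identical(sdannhr24(seg), sdann24(seg))
  noisy <- inject_hr_noise(seg, 3, seed = 1)
  expect_gt(abs(sdannhr24(noisy) - sdann24(noisy)), 0)
  expect_identical(sdann24(noisy), sdann24(seg))
})

test_that("estimators are invariant to a constant timestamp offset", {
  set.seed(6)
  nn <- 900 + rnorm(2000, 0, 70)
  s <- series_from_nn(nn)
  s_off <- beat_series(s$t + 1234, s$nn)
  e1 <- sdnn_estimates(s, 5)
  e2 <- sdnn_estimates(s_off, 5, origin = 1234)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("window-averaging is a low pass: SDANN decreases with window length", {
  g <- generate_beats(generator_profile(seed = 12, ectopic_rate = 0,
                                        gap_rate_per_h = 0))
  sd_by_w <- vapply(c(1, 5, 10, 30, 60),
                    function(w) sdann24(segment_hr(g$clean, w)), numeric(1))
  expect_true(all(diff(sd_by_w) < 0))
  expect_true(all(sd_by_w < sdnn24(g$clean)))
})

test_that("SDNN interpretation bands split at 50 and 100 ms", {
  expect_equal(as.character(classify_sdnn(c(49.9, 50, 75, 100, 100.1, 133.73))),
               c("unhealthy", "compromised", "compromised", "compromised",
                 "healthy", "healthy"))
  expect_error(classify_sdnn(-1), "non-negative")
})
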