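test_that("range filter flags exactly the out-of-bound intervals", {
  s <- beat_series(c(0.8, 1.05, 1.95), c(800, 250, 900), validate = FALSE)
  expect_equal(flag_outliers(s), c(FALSE, TRUE, FALSE))
  expect_false(any(flag_outliers(series_from_nn(c(800, 900, 1000)))))
  expect_true(flag_outliers(series_from_nn(c(800, 2001)))[2])
  expect_false(flag_outliers(series_from_nn(c(800, 2000)))[2])
})

test_that("ectopic rule flags relative jumps from the previous clean beat", {
  expect_false(any(flag_ectopic(series_from_nn(c(800, 800, 800)))))
  expect_equal(flag_ectopic(series_from_nn(c(800, 1000))), c(FALSE, TRUE))
  expect_error(flag_ectopic(series_from_nn(1000)), "at least 2")
})

test_that("isolated ectopics on a smooth base are flagged exactly", {
  set.seed(21)
  for (rep in 1:5) {
    nn <- 800 + 60 * sin(2 * pi * (1:400) / 150)  # smooth drift, <1% per beat
    inj <- sort(sample(5:395, 12))
    inj <- inj[c(TRUE, diff(inj) > 3)]            # keep them isolated
    nn[inj] <- nn[inj] * sample(c(0.55, 1.45), length(inj), replace = TRUE)
    got <- flag_ectopic(series_from_nn(nn))
    expect_identical(which(got), inj)
  }
})

test_that("a slipped ectopic reference is retro-flagged, not its successors", {
  # 1150 slips under the threshold against the elevated 990 reference; the
  # return to ~840 must expose it as the anomaly
  nn <- c(980, 990, 1150, 840, 850, 845, 850)
  got <- flag_ectopic(series_from_nn(nn))
  expect_identical(which(got), 3L)
})

test_that("a corrupt leading beat cannot poison the whole record", {
  nn <- c(1500, 800, 810, 805, 820, 815, 808, 812)
  got <- flag_ectopic(series_from_nn(nn))
  # three beats pay for the bad reference, then the rule resynchronises
  expect_identical(which(got), c(2L, 3L, 4L))
})

test_that("quadratic interpolation matches an independent polynomial fit", {
  set.seed(4)
  nn <- 800 + rnorm(30, 0, 20)
  s <- series_from_nn(nn)
  mask <- rep(FALSE, 30); mask[15] <- TRUE
  out <- interpolate_flagged(s, mask)
  sup <- c(13, 14, 16, 17)
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = s$t[sup], y = nn[sup]))
  want <- unname(predict(fit, newdata = data.frame(x = s$t[15])))
  expect_equal(out$nn[15], want, tolerance = 1e-9)
  expect_equal(out$quality_flags[15], "interpolated")
})

test_that("interpolation reproduces an exactly quadratic profile", {
  t0 <- cumsum(rep(900, 40)) / 1000
  nn <- 900 + 0.5 * t0 + 0.02 * t0^2
  s <- beat_series(t0, nn, validate = FALSE)
  mask <- rep(FALSE, 40); mask[20] <- TRUE
  out <- interpolate_flagged(s, mask)
  expect_equal(out$nn[20], nn[20], tolerance = 1e-9)
})

test_that("interpolation with nothing flagged is the identity", {
  s <- series_from_nn(800 + sin(1:50))
  expect_identical(interpolate_flagged(s, rep(FALSE, 50)), s)
})

test_that("long flagged runs are dropped, not fabricated", {
  nn <- rep(800, 60)
  nn[20:35] <- 5000  # 16 beats, ~80 s: far beyond the 10 s limit
  s <- series_from_nn(nn)
  mask <- flag_outliers(s)
  out <- interpolate_flagged(s, mask)
  expect_equal(length(out$nn), 44L)
  expect_false(any(out$quality_flags == "interpolated"))
  expect_silent(validate_beat_series(out))
})

test_that("a clean series passes through preprocessing untouched", {
  g <- generate_beats(generator_profile(seed = 5, ectopic_rate = 0,
                                        gap_rate_per_h = 0, duration_h = 2))
  res <- preprocess(g$series)
  expect_equal(res$report$pct_flagged, 0)
  expect_equal(res$series$nn, g$series$nn)
  expect_equal(res$series$t, g$series$t)
})

test_that("injected ectopics are flagged near the injected rate and repaired", {
  g <- generate_beats(generator_profile(seed = 8, gap_rate_per_h = 0))
  res <- preprocess(g$series)
  expect_gte(res$report$pct_flagged, 1.5)
  expect_lte(res$report$pct_flagged, 3.5)
  # repaired series recovers the ground-truth SDNN24 within 5%
  expect_lt(abs(sdnn24(res$series) - sdnn24(g$clean)) / sdnn24(g$clean), 0.05)
})

test_that("preprocessing is idempotent on smooth inputs", {
  g <- generate_beats(generator_profile(seed = 9, gap_rate_per_h = 0,
                                        duration_h = 4))
  once <- preprocess(g$series)
  twice <- preprocess(once$series)
  expect_equal(twice$report$n_outlier, 0L)
  expect_equal(twice$report$pct_flagged, 0)
})

test_that("estimator error shrinks as the injected ectopic rate shrinks", {
  errs <- vapply(c(0.06, 0.02, 0), function(rate) {
    g <- generate_beats(generator_profile(seed = 31, ectopic_rate = rate,
                                          gap_rate_per_h = 0))
    abs(sdnn24(preprocess(g$series)$series) - sdnn24(g$clean))
  }, numeric(1))
  expect_true(all(diff(errs) <= 0.5))
  # with nothing injected, at most the odd marginal beat is touched
  expect_lt(errs[3], 0.01)
})
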