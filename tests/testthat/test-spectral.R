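int_psd <- function(psd) {
  f <- psd$freqs_hz; p <- psd$power_ms2_per_hz
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

test_that("a pure sinusoid integrates to A^2/2 total power", {
  s <- sinusoid_series(amp_ms = 50, f_hz = 0.01, duration_s = 7200)
  psd <- lomb_scargle_psd(s, grid = "linear", n_freqs = 20000)
  expect_lt(abs(int_psd(psd) - 1250) / 1250, 0.05)
})

test_that("white noise satisfies the variance (Parseval) identity", {
  set.seed(2)
  nn <- 1000 + rnorm(4096, 0, 30)
  s <- beat_series(cumsum(rep(1000, 4096)) / 1000, nn, validate = FALSE)
  psd <- lomb_scargle_psd(s, grid = "linear", n_freqs = 8192)
  expect_lt(abs(int_psd(psd) - 900) / 900, 0.10)
  # and against the realised time-domain variance, tighter
  expect_lt(abs(int_psd(psd) - psd$var_ms2) / psd$var_ms2, 0.05)
})

test_that("a constant series yields a zero spectrum", {
  s <- series_from_nn(rep(1000, 100))
  psd <- lomb_scargle_psd(s)
  expect_true(all(psd$power_ms2_per_hz == 0))
})

test_that("pure tones land in their HRV band", {
  for (case in list(list(f = 0.001, band = "ulf_ms2"),
                    list(f = 0.1, band = "lf_ms2"),
                    list(f = 0.25, band = "hf_ms2"))) {
    s <- sinusoid_series(amp_ms = 40, f_hz = case$f, duration_s = 14400,
                         dt_ms = 800)
    bp <- band_powers(lomb_scargle_psd(s, grid = "linear", n_freqs = 30000))
    total <- bp$ulf_ms2 + bp$vlf_ms2 + bp$lf_ms2 + bp$hf_ms2
    expect_gt(bp[[case$band]] / total, 0.95)
  }
})

test_that("band powers add up to the integral over their union", {
  g <- generate_beats(generator_profile(seed = 3, ectopic_rate = 0,
                                        gap_rate_per_h = 0, duration_h = 6))
  psd <- lomb_scargle_psd(g$series, n_freqs = 800)
  bp <- band_powers(psd)
  edges <- default_band_edges()
  union_int <- integrate_union <- local({
    # brute-force trapezoid over the contiguous union [1/86400, 1/2]
    f <- psd$freqs_hz; p <- psd$power_ms2_per_hz
    lo <- max(edges$ulf[1], f[1]); hi <- min(edges$hf[2], f[length(f)])
    inside <- f > lo & f < hi
    fi <- c(lo, f[inside], hi)
    pi_ <- c(approx(f, p, xout = lo)$y, p[inside], approx(f, p, xout = hi)$y)
    sum(diff(fi) * (pi_[-1] + pi_[-length(pi_)]) / 2)
  })
  got <- bp$ulf_ms2 + bp$vlf_ms2 + bp$lf_ms2 + bp$hf_ms2
  expect_equal(got, union_int, tolerance = 1e-9)
  expect_lte(got, bp$total_ms2 + 1e-9)
})

test_that("window cutoff frequencies are 1/(60 w)", {
  expect_equal(cutoff_frequency(1), 1 / 60)        # 0.01667 Hz
  expect_equal(cutoff_frequency(5), 1 / 300)       # 0.00333 Hz
  expect_equal(cutoff_frequency(10), 1 / 600)
  expect_equal(cutoff_frequency(30), 1 / 1800)
  expect_equal(cutoff_frequency(60), 1 / 3600)     # 2.78e-4 Hz
  expect_equal(round(cutoff_frequency(1), 3), 0.017)
  expect_error(cutoff_frequency(-5), "positive")
})

test_that("a-priori spectrum is the pointwise cohort mean", {
  set.seed(9)
  nn <- 900 + rnorm(2400, 0, 60)
  s <- series_from_nn(nn)
  ap <- build_apriori_spectrum(list(s, s, s), n_freqs = 400)
  psd <- lomb_scargle_psd(s, f_min = min(ap$freqs_hz), n_freqs = 400)
  expect_equal(ap$mean_power_ms2_per_hz, psd$power_ms2_per_hz)

  s0 <- series_from_nn(rep(900, 2400))  # zero-variance subject
  ap2 <- build_apriori_spectrum(list(s, s0), n_freqs = 400,
                                f_min = min(ap$freqs_hz))
  expect_equal(ap2$mean_power_ms2_per_hz, psd$power_ms2_per_hz / 2)
  # cumulative power is monotone, ends at the grid integral, and the
  # Parseval-exact total agrees with it within the normalisation tolerance
  cp <- ap$cumulative_power(ap$freqs_hz)
  expect_true(all(diff(cp) >= 0))
  expect_equal(cp[length(cp)], ap$grid_total_ms2)
  expect_lt(abs(ap$grid_total_ms2 - ap$total_ms2) / ap$total_ms2, 0.1)
  expect_equal(ap$total_ms2, mean((s$nn - mean(s$nn))^2))
})

test_that("corrections follow their closed forms and only add power", {
  # flat synthetic reference spectrum with a known low/high split
  flat_apriori <- function(total, f_lo = 0.001, f_hi = 0.501) {
    f <- seq(f_lo, f_hi, length.out = 2001)
    d <- rep(total / (f_hi - f_lo), 2001)
    cum <- c(0, cumsum(diff(f) * (d[-1] + d[-2001]) / 2))
    structure(list(freqs_hz = f, mean_power_ms2_per_hz = d,
                   cohort_ids = "flat", total_ms2 = cum[2001],
                   cumulative_power = approxfun(f, cum, rule = 2)),
              class = "apriori_spectrum")
  }
  # adj_mean: missing power 44 on measured variance 100 -> sqrt(144)
  ap <- flat_apriori(total = 100)
  fc_at <- function(frac) 0.001 + frac * 0.5      # cutoff at a power fraction
  w_for <- function(fc) 1 / (60 * fc)
  expect_equal(adj_mean(100, w_for(fc_at(0.56)), ap), 12, tolerance = 1e-6)
  expect_equal(adj_mean(100, w_for(0.501), ap), 10, tolerance = 1e-3)
  # adj_w sharp cutoff: low:high split 20:80 on measured 100 -> sqrt(500)
  expect_equal(adj_w(100, w_for(fc_at(0.20)), ap, transfer = "sharp"),
               sqrt(500), tolerance = 1e-6)
  expect_equal(adj_w(100, w_for(0.501), ap, transfer = "sharp"), 10,
               tolerance = 1e-3)
  # corrections never shrink the estimate
  for (frac in c(0.1, 0.5, 0.9)) {
    w <- w_for(fc_at(frac))
    expect_gte(adj_mean(100, w, ap), 10)
    expect_gte(adj_w(100, w, ap), 10)
    expect_gte(adj_w(100, w, ap, transfer = "sharp"), 10)
  }
  expect_error(adj_mean(100, 1 / (60 * 0.7), ap), "above the a-priori grid")
})

test_that("adj_w is scale-equivariant under cohort rescaling", {
  set.seed(30)
  t <- cumsum(rep(900, 1800)) / 1000
  devs <- replicate(3, rnorm(1800, 0, 50), simplify = FALSE)
  mk <- function(scale) lapply(devs, function(d)
    beat_series(t, 900 + scale * d, validate = FALSE))
  ap1 <- build_apriori_spectrum(mk(1), n_freqs = 300)
  ap2 <- build_apriori_spectrum(mk(3), n_freqs = 300)
  v <- 400
  expect_equal(adj_w(9 * v, 5, ap2), 3 * adj_w(v, 5, ap1), tolerance = 1e-6)
})
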