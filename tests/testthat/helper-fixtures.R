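# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# beat series with consistent timestamps from a vector of NN intervals (ms)
series_from_nn <- function(nn, subject_id = "fix") {
  beat_series(cumsum(nn) / 1000, nn, subject_id = subject_id)
}

# evenly sampled sinusoidal NN series: nn(t) = mean + amp*sin(2*pi*f*t)
sinusoid_series <- function(mean_ms = 1000, amp_ms = 50, f_hz = 0.01,
                            duration_s = 7200, dt_ms = 1000) {
  t <- seq(dt_ms / 1000, duration_s, by = dt_ms / 1000)
  nn <- mean_ms + amp_ms * sin(2 * pi * f_hz * t)
  beat_series(t, nn, validate = FALSE)
}

# Equal-beat-count segmentation fixture: `k` blocks of `m` beats (m odd),
# each block summing exactly to `m * base_ms` (deviations come in +/- pairs),
# so 60*`m*base_ms/60000`-min windows tiling from the first beat time hold
# exactly m beats each. The first beat carries the strictly smallest
# deviation (-70 ms vs. |others| <= 60) so no beat crosses its window
# boundary.
equal_count_series <- function(k = 40, m = 75, base_ms = 800, seed = 7) {
  stopifnot(m %% 2 == 1)
  set.seed(seed)
  np <- (m - 1) %/% 2
  block_dev <- function(first) {
    if (first) {
      d <- runif(np - 1, 5, 60)
      c(-70, 70, sample(c(d, -d, 0)))
    } else {
      d <- runif(np, 5, 60)
      sample(c(d, -d, 0))
    }
  }
  nn <- unlist(lapply(seq_len(k), function(b) base_ms + block_dev(b == 1)))
  series_from_nn(nn)
}

trapz_test <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

metric_of <- function(report, cls, what = "f1") {
  report$metrics[[what]][report$metrics$class == cls]
}
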