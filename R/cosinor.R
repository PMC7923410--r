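#' Fit a fixed-period cosinor model to heart-rate samples
#'
#' Fits `HR(t) = M + A*cos(2*pi*(t/T + phi)) + e` at a fixed period `T`
#' (24 h by default) by least squares via the linearisation
#' `HR = M + beta*cos(2*pi*t/T) + gamma*sin(2*pi*t/T)`, recovering
#' `A = sqrt(beta^2 + gamma^2)` and `phi = atan2(-gamma, beta)/(2*pi) mod 1`.
#' M is the MESOR (rhythm-adjusted mean), A the amplitude (half the
#' predictable within-cycle excursion) and phi the acrophase in cycles.
#' Optional extra harmonics (e.g. a 12-h component) can be included; their
#' amplitudes are reported but the primary M, A, phi always refer to the
#' fundamental period.
#'
#' @param times_s Sample times in seconds (at least 4, spanning at least half
#'   a period).
#' @param hr_bpm Heart-rate samples in bpm.
#' @param period_h Fundamental period in hours (default 24).
#' @param harmonics_h Optional vector of additional periods in hours.
#' @return A `cosinor_fit`: `mesor_bpm`, `amplitude_bpm`, `acrophase_cycles`
#'   in `[0, 1)`, `peak_time_h` (time of peak HR after record start, hours),
#'   `period_h`, `residual_sd_bpm`, `n`, and `harmonics` (data frame, possibly
#'   empty).
#' @examples
#' t <- seq(0, 86400, by = 300)
#' hr <- 70 + 10 * cos(2 * pi * t / 86400)
#' fit_cosinor(t, hr)
#' @export
fit_cosinor <- function(times_s, hr_bpm, period_h = 24, harmonics_h = NULL) {
  if (length(times_s) != length(hr_bpm))
    stop_validation("times and HR must have equal length")
  ok <- is.finite(times_s) & is.finite(hr_bpm)
  times_s <- times_s[ok]; hr_bpm <- hr_bpm[ok]
  n <- length(times_s)
  if (n < 4L) stop_validation("cosinor fit needs at least 4 samples")
  T_s <- period_h * 3600
  if (diff(range(times_s)) < T_s / 2)
    stop_validation("samples must span at least half a period (%.1f h)", period_h / 2)

  w <- 2 * pi * times_s / T_s
  X <- cbind(1, cos(w), sin(w))
  cn <- c("(Intercept)", "c1", "s1")
  for (h in harmonics_h) {
    wh <- 2 * pi * times_s / (h * 3600)
    X <- cbind(X, cos(wh), sin(wh))
    cn <- c(cn, sprintf("c_%gh", h), sprintf("s_%gh", h))
  }
  colnames(X) <- cn
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop_validation("rank-deficient cosinor design (samples concentrated at one phase)")
  fit <- stats::lm.fit(X, hr_bpm)
  b <- fit$coefficients
  beta <- b[["c1"]]; gam <- b[["s1"]]
  A <- sqrt(beta^2 + gam^2)
  phi <- (atan2(-gam, beta) / (2 * pi)) %% 1
  res <- fit$residuals
  harm <- data.frame(period_h = numeric(0), amplitude_bpm = numeric(0))
  for (h in harmonics_h) {
    bh <- b[[sprintf("c_%gh", h)]]; sh <- b[[sprintf("s_%gh", h)]]
    harm <- rbind(harm, data.frame(period_h = h,
                                   amplitude_bpm = sqrt(bh^2 + sh^2)))
  }
  structure(list(mesor_bpm = b[["(Intercept)"]], amplitude_bpm = A,
                 acrophase_cycles = phi,
                 peak_time_h = ((1 - phi) %% 1) * period_h,
                 period_h = period_h,
                 residual_sd_bpm = if (n > ncol(X)) sd(res) else 0,
                 n = n, harmonics = harm),
            class = "cosinor_fit")
}

#' Fit the circadian cosinor to a segmented-HR record
#'
#' Convenience wrapper: fits [fit_cosinor()] to the per-window heart rates at
#' the window mid-times.
#'
#' @param segments A [segment_hr()] result.
#' @param period_h Period in hours (default 24).
#' @param ... Passed to [fit_cosinor()].
#' @return A `cosinor_fit`.
#' @export
cosinor_from_segments <- function(segments, period_h = 24, ...) {
  stopifnot(inherits(segments, "segmented_hr"))
  mid <- segments$segments$start_s + 30 * segments$window_min
  fit_cosinor(mid, segments$segments$mean_hr_bpm, period_h = period_h, ...)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("<cosinor_fit> MESOR %.2f bpm, amplitude %.2f bpm, acrophase %.3f cycles (peak at %.2f h), residual SD %.2f bpm (n=%d, T=%g h)\n",
              x$mesor_bpm, x$amplitude_bpm, x$acrophase_cycles, x$peak_time_h,
              x$residual_sd_bpm, x$n, x$period_h))
  invisible(x)
}
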