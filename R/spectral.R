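# Lomb-Scargle spectral analysis of the unevenly sampled NN series, HRV band
# powers, and the two window-loss bias corrections driven by an a-priori
# cohort spectrum.

#' Lomb-Scargle power spectral density of a beat series
#'
#' Computes the Lomb-Scargle periodogram of the NN-interval series at its
#' native (uneven) beat sampling, and scales it to a one-sided density over
#' frequency in Hz under the *variance* normalisation contract: the
#' trapezoidal integral of the density over the full evaluated band equals
#' (approximately) the time-domain variance of the NN series in ms^2. This is
#' the frequency-domain identity that lets total spectral power stand in for
#' SDNN^2.
#'
#' The density is `S(f) = 2 * P(f) * T / N` where `P` is the classic
#' unnormalised periodogram of the mean-subtracted series, `T` the record
#' span and `N` the number of beats (`N/T` being the effective sampling
#' rate).
#'
#' @param series A [beat_series()].
#' @param f_min,f_max Frequency range in Hz; defaults to `1/span` to 0.5 Hz.
#' @param n_freqs Number of grid points (default 2000).
#' @param grid `"log"` (default; resolves the >4 decades of a 1/f-shaped
#'   spectrum) or `"linear"` (fine uniform grid, preferred for narrow-band
#'   total-power checks).
#' @return A `psd_estimate`: list with `freqs_hz`, `power_ms2_per_hz`,
#'   `normalisation = "variance"`, `span_s`, `n_beats`, `var_ms2`.
#' @export
lomb_scargle_psd <- function(series, f_min = NULL, f_max = 0.5,
                             n_freqs = 2000, grid = c("log", "linear")) {
  stopifnot(inherits(series, "beat_series"))
  grid <- match.arg(grid)
  n <- length(series$t)
  if (n < 16L) stop_validation("need at least 16 beats for a PSD")
  span <- max(series$t) - min(series$t)
  if (span <= 0) stop_validation("degenerate record span")
  if (is.null(f_min)) f_min <- 1 / span
  if (f_min <= 0 || f_max <= f_min)
    stop_validation("require 0 < f_min < f_max")
  freqs <- switch(grid,
    log = exp(seq(log(f_min), log(f_max), length.out = n_freqs)),
    linear = seq(f_min, f_max, length.out = n_freqs))
  y <- series$nn - mean(series$nn)
  v <- if (n > 1L) sum(y^2) / n else 0
  if (v == 0) {
    power <- rep(0, n_freqs)
  } else {
    p <- ls_power_cpp(series$t, y, freqs)
    power <- 2 * p * span / n
  }
  structure(list(freqs_hz = freqs, power_ms2_per_hz = power,
                 normalisation = "variance", span_s = span, n_beats = n,
                 var_ms2 = v),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d freqs in [%.2e, %.2e] Hz; integral %.0f ms^2 (time-domain var %.0f ms^2)\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              trapz(x$freqs_hz, x$power_ms2_per_hz), x$var_ms2))
  invisible(x)
}

#' Plot a PSD estimate on log-log axes
#'
#' @param x A `psd_estimate`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psd_estimate <- function(x, ...) {
  pos <- x$power_ms2_per_hz > 0
  graphics::plot(x$freqs_hz[pos], x$power_ms2_per_hz[pos], type = "l",
                 log = "xy", xlab = "frequency [Hz]",
                 ylab = "PSD [ms^2/Hz]", ...)
  invisible(x)
}

#' Default HRV band edges
#'
#' ULF: periods 5 min to 24 h; VLF: 25 s to 5 min; LF: 7 to 25 s; HF: 2 to
#' 7 s — expressed in Hz.
#'
#' @return Named list of `c(lo, hi)` frequency pairs in Hz.
#' @export
default_band_edges <- function() {
  list(ulf = c(1 / 86400, 1 / 300),
       vlf = c(1 / 300, 1 / 25),
       lf = c(1 / 25, 1 / 7),
       hf = c(1 / 7, 1 / 2))
}

# Trapezoidal integral of a PSD between lo and hi, with linear interpolation
# at the edges.
integrate_psd <- function(psd, lo, hi) {
  f <- psd$freqs_hz; p <- psd$power_ms2_per_hz
  if (lo >= hi) stop_validation("empty integration band [%g, %g]", lo, hi)
  lo <- max(lo, f[1L]); hi <- min(hi, f[length(f)])
  if (lo >= hi) return(0)
  inside <- f > lo & f < hi
  fi <- c(lo, f[inside], hi)
  pi_ <- c(approx(f, p, xout = lo)$y, p[inside], approx(f, p, xout = hi)$y)
  trapz(fi, pi_)
}

#' Integrate a PSD over the standard HRV bands
#'
#' @param psd A [lomb_scargle_psd()] result.
#' @param edges Band definitions as in [default_band_edges()]. Edges must lie
#'   within the evaluated grid (they are clipped to it; fully outside is an
#'   error).
#' @return A `band_powers` list: `ulf_ms2`, `vlf_ms2`, `lf_ms2`, `hf_ms2`,
#'   `total_ms2` (integral over the full grid) and `band_edges_hz`.
#' @export
band_powers <- function(psd, edges = default_band_edges()) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$freqs_hz
  for (nm in names(edges)) {
    e <- edges[[nm]]
    if (e[2L] <= f[1L] || e[1L] >= f[length(f)])
      stop_validation("band '%s' [%g, %g] lies outside the PSD grid", nm, e[1L], e[2L])
  }
  p <- lapply(edges, function(e) integrate_psd(psd, e[1L], e[2L]))
  structure(list(ulf_ms2 = p$ulf, vlf_ms2 = p$vlf, lf_ms2 = p$lf,
                 hf_ms2 = p$hf,
                 total_ms2 = trapz(f, psd$power_ms2_per_hz),
                 band_edges_hz = edges),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> ULF %.0f, VLF %.0f, LF %.0f, HF %.0f, total %.0f ms^2\n",
              x$ulf_ms2, x$vlf_ms2, x$lf_ms2, x$hf_ms2, x$total_ms2))
  invisible(x)
}

#' Highest frequency observable after window averaging
#'
#' Averaging HR over windows of `w` minutes acts as a low-pass filter; the
#' windowed series resolves only frequencies below `1/(60*w)` Hz (0.0167,
#' 0.00333 and 0.00167 Hz for 1, 5 and 10 min windows).
#'
#' @param window_min Window length in minutes, positive (vectorised).
#' @return Cutoff frequency in Hz.
#' @export
cutoff_frequency <- function(window_min) {
  if (any(window_min <= 0)) stop_validation("window_min must be positive")
  1 / (60 * window_min)
}

#' Build an a-priori cohort-average spectrum
#'
#' Computes each subject's Lomb-Scargle PSD on a common frequency grid and
#' averages them pointwise. The resulting reference spectrum supplies the
#' "missing high-frequency power" terms of the window-loss corrections
#' [adj_mean()] and [adj_w()]; building it on a *separate* cohort from the
#' one being corrected avoids using the same data to estimate and to correct.
#'
#' @param cohort List of [beat_series()] (at least 2).
#' @param f_min,f_max,n_freqs,grid Grid specification as in
#'   [lomb_scargle_psd()]; `f_min` defaults to the largest `1/(2*span)`
#'   across the cohort — half an octave below the fundamental, so the
#'   spectral line of a circadian oscillation (width ~1/span, centred at
#'   1/86400 Hz for a 24-h record) is integrated in full rather than cut in
#'   half at the grid edge, which would bias the correction ratios.
#' @return An `apriori_spectrum`: `freqs_hz`, `mean_power_ms2_per_hz`,
#'   `cohort_ids`, `total_ms2`, and `cumulative_power(f)` (a function giving
#'   the integral of the mean density from the grid start to `f`).
#'
#' @details `total_ms2` is the cohort mean of the *time-domain* NN variances
#' (Parseval-exact) rather than the grid integral of the mean density: narrow
#' spectral lines (e.g. near-sinusoidal LF/HF oscillations, width `1/span`)
#' are under-resolved on any practical frequency grid, and their power must
#' still be counted in the total that the corrections redistribute. The grid
#' integral agrees with `total_ms2` to within the density normalisation
#' tolerance; the difference is the unresolved line content.
#' @export
build_apriori_spectrum <- function(cohort, f_min = NULL, f_max = 0.5,
                                   n_freqs = 2000, grid = "log") {
  if (length(cohort) < 2L) stop_validation("a-priori spectrum needs >= 2 subjects")
  stopifnot(all(vapply(cohort, inherits, logical(1), "beat_series")))
  if (is.null(f_min))
    f_min <- max(vapply(cohort, function(s) 0.5 / (max(s$t) - min(s$t)), numeric(1)))
  psds <- lapply(cohort, lomb_scargle_psd, f_min = f_min, f_max = f_max,
                 n_freqs = n_freqs, grid = grid)
  freqs <- psds[[1L]]$freqs_hz
  mp <- Reduce(`+`, lapply(psds, `[[`, "power_ms2_per_hz")) / length(psds)
  cum <- cumtrapz(freqs, mp)
  cpf <- approxfun(freqs, cum, rule = 2)
  total <- mean(vapply(psds, `[[`, numeric(1), "var_ms2"))
  structure(list(freqs_hz = freqs, mean_power_ms2_per_hz = mp,
                 cohort_ids = vapply(cohort, `[[`, character(1), "subject_id"),
                 total_ms2 = total,
                 grid_total_ms2 = cum[length(cum)],
                 cumulative_power = cpf),
            class = "apriori_spectrum")
}

#' @export
print.apriori_spectrum <- function(x, ...) {
  cat(sprintf("<apriori_spectrum> %d subjects, %d freqs in [%.2e, %.2e] Hz, total %.0f ms^2\n",
              length(x$cohort_ids), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), x$total_ms2))
  invisible(x)
}

# a-priori power above a cutoff frequency
apriori_power_above <- function(apriori, f) {
  stopifnot(inherits(apriori, "apriori_spectrum"))
  if (f > max(apriori$freqs_hz))
    stop_validation("cutoff %.4g Hz above the a-priori grid maximum %.4g Hz",
                    f, max(apriori$freqs_hz))
  apriori$total_ms2 - apriori$cumulative_power(f)
}

#' Additive window-loss correction (fixed cohort-mean power)
#'
#' Corrects the underestimation of SDNN24 by a windowed estimator by *adding*
#' the cohort-average spectral power above the window's cutoff frequency to
#' the measured variance — a corrective term that is the same for every
#' subject:
#' `sqrt(var_measured + P_apriori(f > 1/(60*w)))`.
#'
#' @param measured_var_ms2 Variance of the windowed ANN series, ms^2.
#' @param window_min Window length in minutes.
#' @param apriori An [build_apriori_spectrum()] result.
#' @return Corrected SDNN estimate in ms.
#' @export
adj_mean <- function(measured_var_ms2, window_min, apriori) {
  if (any(measured_var_ms2 < 0)) stop_validation("measured variance must be >= 0")
  fc <- cutoff_frequency(window_min)
  sqrt(measured_var_ms2 + apriori_power_above(apriori, fc))
}

# a-priori power retained by a boxcar window mean of length w minutes:
# integral of S(f) * sinc^2(pi f w) over the grid. This is the expected
# variance of the windowed-mean series for a signal with the a-priori
# spectrum (attenuation below the cutoff and sidelobe leakage above it both
# included).
apriori_retained_power <- function(apriori, window_min) {
  stopifnot(inherits(apriori, "apriori_spectrum"))
  w_s <- 60 * window_min
  x <- pi * apriori$freqs_hz * w_s
  sinc2 <- ifelse(x == 0, 1, (sin(x) / x)^2)
  trapz(apriori$freqs_hz, apriori$mean_power_ms2_per_hz * sinc2)
}

#' Multiplicative window-loss correction (spectral-shape rescaling)
#'
#' Corrects the underestimation by assuming the missing high frequencies are
#' perfectly correlated with the measured low frequencies: the measured
#' variance is rescaled by the ratio of the a-priori total power to the
#' a-priori power the windowed measurement retains.
#'
#' With `transfer = "sinc"` (the default) the retained power is the a-priori
#' density weighted by the squared frequency response of the boxcar window
#' mean, `sinc^2(pi f w)` — the actual low-pass the averaging applies, which
#' accounts for the attenuation of frequencies below but near the cutoff as
#' well as sidelobe leakage above it. With `transfer = "sharp"` the window is
#' idealised as a brick wall at [cutoff_frequency()]:
#' `sqrt(var_measured * (1 + P_high/P_low))` with `P_low` the a-priori power
#' below the cutoff.
#'
#' @inheritParams adj_mean
#' @param transfer `"sinc"` (boxcar frequency response, default) or
#'   `"sharp"` (ideal cutoff).
#' @return Corrected SDNN estimate in ms.
#' @export
adj_w <- function(measured_var_ms2, window_min, apriori,
                  transfer = c("sinc", "sharp")) {
  if (any(measured_var_ms2 < 0)) stop_validation("measured variance must be >= 0")
  transfer <- match.arg(transfer)
  if (transfer == "sharp") {
    fc <- cutoff_frequency(window_min)
    p_high <- apriori_power_above(apriori, fc)
    p_low <- apriori$total_ms2 - p_high
    if (p_low <= 0) stop_validation("a-priori power below the cutoff is zero")
    return(sqrt(measured_var_ms2 * (1 + p_high / p_low)))
  }
  p_ret <- apriori_retained_power(apriori, window_min)
  if (p_ret <= 0) stop_validation("a-priori power retained by the window is zero")
  sqrt(measured_var_ms2 * apriori$total_ms2 / p_ret)
}
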