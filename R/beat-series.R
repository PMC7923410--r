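#' Construct a beat series
#'
#' A `beat_series` is the package's primary signal: a 24-hour (or shorter)
#' sequence of heart beats, each carrying the timestamp of the beat in seconds
#' since record start and the NN interval ending at that beat in milliseconds.
#'
#' Canonical units throughout the package are seconds for timestamps,
#' milliseconds for NN intervals, beats per minute for heart rate, ms^2 for
#' spectral power and Hz for frequency.
#'
#' @param t Numeric vector of beat timestamps, seconds since record start,
#'   strictly increasing.
#' @param nn Numeric vector of NN intervals in milliseconds, one per beat;
#'   `nn[i]` is the interval ending at `t[i]`.
#' @param subject_id Character scalar identifying the subject.
#' @param quality_flags Optional character vector of per-beat flags, one of
#'   `"normal"`, `"outlier"`, `"ectopic"`, `"interpolated"`.
#' @param start_time Optional ISO 8601 record start time, carried as metadata
#'   only (acrophase reporting); timestamps stay relative.
#' @param validate Run the invariant checks (default `TRUE`).
#'
#' @return An object of class `beat_series`: a list with elements `subject_id`,
#'   `t`, `nn`, `quality_flags`, `start_time`.
#'
#' @details Timestamp/interval consistency requires `|(t[i] - t[i-1])*1000 -
#' nn[i]| <= 1` ms for consecutive beats. A larger *positive* timestamp gap
#' (`dt*1000 > nn + 1`) is interpreted as a true recording gap (beats were
#' dropped) and is allowed; a *negative* mismatch (intervals overlapping their
#' timestamps) is a validation error.
#' @export
beat_series <- function(t, nn, subject_id = "subject", quality_flags = NULL,
                        start_time = NULL, validate = TRUE) {
  t <- as.numeric(t)
  nn <- as.numeric(nn)
  if (length(t) != length(nn))
    stop_validation("t and nn must have equal length (%d vs %d)", length(t), length(nn))
  if (is.null(quality_flags)) quality_flags <- rep("normal", length(t))
  x <- structure(
    list(subject_id = as.character(subject_id)[1L], t = t, nn = nn,
         quality_flags = quality_flags, start_time = start_time),
    class = "beat_series")
  if (validate) validate_beat_series(x)
  x
}

#' Validate a beat series against its invariants
#'
#' Checks strictly increasing timestamps, positive NN intervals, and
#' timestamp/interval consistency (see [beat_series()] for the gap rule).
#'
#' @param x A `beat_series`.
#' @param tol_ms Consistency tolerance in milliseconds (default 1).
#' @return `x`, invisibly; errors on violation.
#' @export
validate_beat_series <- function(x, tol_ms = 1) {
  if (!inherits(x, "beat_series")) stop_validation("not a beat_series")
  n <- length(x$t)
  if (n == 0L) stop_validation("beat series is empty")
  if (any(!is.finite(x$t)) || any(!is.finite(x$nn)))
    stop_validation("non-finite timestamps or NN intervals")
  if (n > 1L && any(diff(x$t) <= 0))
    stop_validation("timestamps must be strictly increasing (first violation at beat %d)",
                    which(diff(x$t) <= 0)[1L] + 1L)
  if (any(x$nn <= 0))
    stop_validation("all NN intervals must be positive")
  if (n > 1L) {
    dt_ms <- diff(x$t) * 1000
    # overlap: the stated interval is longer than the time actually elapsed
    bad <- dt_ms < x$nn[-1L] - tol_ms
    if (any(bad))
      stop_validation("timestamp/interval inconsistency at beat %d (dt=%.1f ms < nn=%.1f ms)",
                      which(bad)[1L] + 1L, dt_ms[which(bad)[1L]], x$nn[-1L][which(bad)[1L]])
  }
  invisible(x)
}

#' Record span of a beat series
#'
#' @param x A `beat_series`.
#' @return Span in seconds from the start of the first interval to the last
#'   beat, i.e. `max(t) - (t[1] - nn[1]/1000)`.
#' @export
beat_span_s <- function(x) {
  max(x$t) - (x$t[1L] - x$nn[1L] / 1000)
}

# Guard for estimators with 24-h semantics.
check_span <- function(x, min_hours = 20) {
  if (beat_span_s(x) < min_hours * 3600)
    stop_validation("record spans %.1f h, below the required minimum of %g h",
                    beat_span_s(x) / 3600, min_hours)
  invisible(x)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> subject '%s': %d beats over %.2f h\n",
              x$subject_id, length(x$t), beat_span_s(x) / 3600))
  cat(sprintf("  mean NN %.1f ms, SDNN %.1f ms, flags: %s\n",
              mean(x$nn),
              if (length(x$nn) > 1) pop_sd(x$nn) else 0,
              paste(sprintf("%s=%d", names(table(x$quality_flags)),
                            as.integer(table(x$quality_flags))), collapse = " ")))
  invisible(x)
}

#' Construct a subject record
#'
#' Bundles a beat series with an optional cardiovascular risk label and the
#' NYHA heart-failure class it was derived from.
#'
#' @param beat_series A [beat_series()].
#' @param nyha_class Optional integer 0-4 (New York Heart Association class).
#' @param risk_label Optional `"low"` or `"high"`; when `nyha_class` is given
#'   the label is derived through [label_risk()] and must not contradict it.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(beat_series, nyha_class = NULL, risk_label = NULL) {
  stopifnot(inherits(beat_series, "beat_series"))
  if (!is.null(nyha_class)) {
    derived <- label_risk(nyha_class)
    if (!is.null(risk_label) && !identical(risk_label, derived))
      stop_validation("risk_label '%s' contradicts NYHA class %d (maps to '%s')",
                      risk_label, nyha_class, derived)
    risk_label <- derived
  }
  structure(list(beat_series = beat_series, risk_label = risk_label,
                 nyha_class = nyha_class),
            class = "subject_record")
}
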