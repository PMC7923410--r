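#' Preprocessing configuration
#'
#' Plausibility bounds and the ectopic-beat rule used to clean a beat series
#' before HRV analysis. Defaults are the de-facto HRV standard: NN intervals
#' outside \[300, 2000\] ms are outliers, and a beat differing from the
#' previous clean beat by more than 20% (the Malik rule) is ectopic.
#'
#' @param nn_min_ms Lower NN plausibility bound, ms (default 300).
#' @param nn_max_ms Upper NN plausibility bound, ms (default 2000).
#' @param ectopic_rule Ectopic rule identifier; only `"malik"` is implemented.
#' @param ectopic_threshold Relative-difference threshold, fraction in (0, 1)
#'   (default 0.20).
#' @param max_gap_s Flagged runs spanning more than this many seconds are
#'   dropped as true gaps rather than interpolated (default 10).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(nn_min_ms = 300, nn_max_ms = 2000,
                              ectopic_rule = "malik", ectopic_threshold = 0.20,
                              max_gap_s = 10) {
  if (!(nn_min_ms > 0 && nn_min_ms < nn_max_ms))
    stop_validation("require 0 < nn_min_ms < nn_max_ms")
  if (!(ectopic_threshold > 0 && ectopic_threshold < 1))
    stop_validation("ectopic_threshold must be in (0, 1)")
  ectopic_rule <- match.arg(ectopic_rule, "malik")
  structure(list(nn_min_ms = nn_min_ms, nn_max_ms = nn_max_ms,
                 ectopic_rule = ectopic_rule,
                 ectopic_threshold = ectopic_threshold,
                 interpolation = "quadratic", max_gap_s = max_gap_s),
            class = "preprocess_config")
}

#' Flag out-of-range NN intervals
#'
#' @param series A [beat_series()].
#' @param cfg A [preprocess_config()].
#' @return Logical mask, `TRUE` where `nn < nn_min_ms` or `nn > nn_max_ms`.
#' @export
flag_outliers <- function(series, cfg = preprocess_config()) {
  stopifnot(inherits(series, "beat_series"))
  series$nn < cfg$nn_min_ms | series$nn > cfg$nn_max_ms
}

#' Flag ectopic beats by relative difference from the previous clean beat
#'
#' Under the Malik rule beat `i` is ectopic when its NN interval differs from
#' the previous *clean* beat's interval by more than `ectopic_threshold`
#' (fractionally). The reference is the last beat not already flagged (either
#' by `exclude` or earlier in this pass), so a single ectopic does not cascade
#' into flagging its normal successor. When a beat disagrees with the current
#' reference but agrees with the clean beat *before* it, and the following
#' beat confirms the new level (agrees with the current beat but not with the
#' reference), the reference itself was the anomaly — an ectopic that slipped
#' under the threshold — and is flagged retroactively instead. A staleness
#' guard resynchronises the reference after three consecutive flags so a
#' corrupt leading beat cannot poison the whole record. The first beat is
#' never flagged.
#'
#' @param series A [beat_series()].
#' @param cfg A [preprocess_config()].
#' @param exclude Optional logical mask of beats already flagged (e.g. range
#'   outliers) to skip as references.
#' @return Logical mask of ectopic beats.
#' @export
flag_ectopic <- function(series, cfg = preprocess_config(), exclude = NULL) {
  stopifnot(inherits(series, "beat_series"))
  n <- length(series$nn)
  if (n < 2L) stop_validation("ectopic detection needs at least 2 beats")
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  thr <- cfg$ectopic_threshold
  nn <- series$nn
  ok_idx <- which(!exclude)
  within_thr <- function(a, b) abs(a - b) <= thr * b
  mask <- rep(FALSE, n)
  ref_idx <- NA_integer_   # previous clean beat
  ref2 <- NA_real_         # clean value before the reference
  run <- 0L                # consecutive flags against the same reference
  for (k in seq_along(ok_idx)) {
    i <- ok_idx[k]
    if (is.na(ref_idx)) { ref_idx <- i; next }
    rv <- nn[ref_idx]
    if (!within_thr(nn[i], rv)) {
      nxt <- if (k < length(ok_idx)) nn[ok_idx[k + 1L]] else NA_real_
      if (!is.na(ref2) && within_thr(nn[i], ref2) && !is.na(nxt) &&
          within_thr(nxt, nn[i]) && !within_thr(nxt, rv)) {
        mask[ref_idx] <- TRUE   # confirmed level shift: blame the reference
        ref_idx <- i
        run <- 0L
      } else if (run >= 3L) {
        ref_idx <- i            # stale reference: resynchronise, don't flag
        run <- 0L
      } else {
        mask[i] <- TRUE
        run <- run + 1L
      }
    } else {
      ref2 <- rv
      ref_idx <- i
      run <- 0L
    }
  }
  mask
}

#' Reconstruct flagged beats by quadratic interpolation over time
#'
#' Each interior run of flagged beats is reconstructed by evaluating a
#' least-squares quadratic in the beat timestamp, fitted through the two clean
#' beats on each side of the run (four support points). Leading and trailing
#' flagged beats cannot be interpolated and are dropped. Runs spanning more
#' than `max_gap_s` seconds are treated as honest gaps: their beats are
#' dropped, not fabricated. After replacement, timestamps are recomputed by
#' cumulative sum within each contiguous block so the timestamp/interval
#' invariant holds.
#'
#' @param series A [beat_series()].
#' @param mask Logical mask of beats to reconstruct.
#' @param max_gap_s Maximum interpolatable run span in seconds (default 10).
#' @return A [beat_series()] with reconstructed beats flagged
#'   `"interpolated"`.
#' @export
interpolate_flagged <- function(series, mask, max_gap_s = 10) {
  stopifnot(inherits(series, "beat_series"), length(mask) == length(series$nn))
  if (!any(mask)) return(series)
  if (sum(!mask) < 3L)
    stop_validation("fewer than 3 clean beats; cannot interpolate")

  t <- series$t; nn <- series$nn; flags <- series$quality_flags
  nn_orig <- nn
  keep <- rep(TRUE, length(t))

  # drop leading/trailing flagged beats
  clean_idx <- which(!mask)
  keep[seq_along(t) < clean_idx[1L]] <- FALSE
  keep[seq_along(t) > clean_idx[length(clean_idx)]] <- FALSE

  runs <- rle(mask & keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    span <- t[i1] - t[i0 - 1L]
    if (span > max_gap_s) { keep[i0:i1] <- FALSE; next }
    left <- utils::tail(which(!mask & seq_along(t) < i0), 2L)
    right <- utils::head(which(!mask & seq_along(t) > i1), 2L)
    sup <- c(left, right)
    if (length(sup) < 3L) { keep[i0:i1] <- FALSE; next }
    ts <- t[sup] - t[i0]  # centred for conditioning
    fit <- stats::lm.fit(cbind(1, ts, ts^2), nn[sup])
    te <- t[i0:i1] - t[i0]
    nn[i0:i1] <- fit$coefficients[1L] + fit$coefficients[2L] * te +
      fit$coefficients[3L] * te^2
    flags[i0:i1] <- "interpolated"
  }

  t <- t[keep]; nn <- nn[keep]; flags <- flags[keep]
  nn_orig <- nn_orig[keep]
  # rebuild timestamps by one monotone cumulative pass: consecutive beats
  # advance by the (possibly replaced) NN interval, while true recording
  # gaps -- places where the original timing already exceeded the original
  # interval, including holes left by dropped runs -- keep their original
  # wall-clock duration
  if (length(t) > 1L) {
    dt_ms <- diff(t) * 1000
    is_gap <- dt_ms > nn_orig[-1L] + 1
    adv_ms <- ifelse(is_gap, dt_ms, nn[-1L])
    t <- t[1L] + c(0, cumsum(adv_ms)) / 1000
  }
  beat_series(t, nn, subject_id = series$subject_id, quality_flags = flags,
              start_time = series$start_time)
}

#' Clean a beat series: range filter, ectopic rule, quadratic reconstruction
#'
#' Composition of [flag_outliers()], [flag_ectopic()] and
#' [interpolate_flagged()], returning the cleaned series together with a
#' report of how much was flagged.
#'
#' @param series A [beat_series()].
#' @param cfg A [preprocess_config()].
#' @return A list with elements `series` (cleaned [beat_series()]) and
#'   `report` (class `preprocess_report`: `n_total`, `n_outlier`, `n_ectopic`,
#'   `pct_flagged`, `n_dropped`, `n_interpolated`).
#' @export
preprocess <- function(series, cfg = preprocess_config()) {
  out_mask <- flag_outliers(series, cfg)
  ect_mask <- flag_ectopic(series, cfg, exclude = out_mask)
  mask <- out_mask | ect_mask
  flags <- series$quality_flags
  flags[out_mask] <- "outlier"
  flags[ect_mask & !out_mask] <- "ectopic"
  series$quality_flags <- flags
  cleaned <- interpolate_flagged(series, mask, max_gap_s = cfg$max_gap_s)
  report <- structure(list(
    n_total = length(series$nn),
    n_outlier = sum(out_mask),
    n_ectopic = sum(ect_mask),
    pct_flagged = 100 * sum(mask) / length(series$nn),
    n_dropped = length(series$nn) - length(cleaned$nn),
    n_interpolated = sum(cleaned$quality_flags == "interpolated")
  ), class = "preprocess_report")
  list(series = cleaned, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> %d beats: %d outlier, %d ectopic (%.2f%% flagged); %d interpolated, %d dropped\n",
              x$n_total, x$n_outlier, x$n_ectopic, x$pct_flagged,
              x$n_interpolated, x$n_dropped))
  invisible(x)
}
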