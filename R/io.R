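#' Read a beat-annotation RR file
#'
#' Reads the two plain-text formats beat-annotation exports commonly come in:
#' a two-column file `(timestamp, NN interval)` or a single-column file of NN
#' intervals only (the usual PhysioNet RR export), in which case timestamps
#' are reconstructed by cumulative sum of the intervals. The delimiter is
#' auto-detected among comma, tab and whitespace; a header line is detected
#' and skipped.
#'
#' @param path Path to the file.
#' @param time_unit Unit of the timestamp column, `"seconds"` or
#'   `"milliseconds"`.
#' @param nn_unit Unit of the NN column, `"milliseconds"` or `"seconds"`.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A [beat_series()] with timestamps in seconds and NN intervals in
#'   milliseconds.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("800", "820", "790"), f)
#' read_rr_csv(f)  # t = 0.80, 1.62, 2.41 s
#' @export
read_rr_csv <- function(path, time_unit = c("seconds", "milliseconds"),
                        nn_unit = c("milliseconds", "seconds"),
                        subject_id = NULL) {
  time_unit <- match.arg(time_unit)
  nn_unit <- match.arg(nn_unit)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_validation("no data rows in %s", path)

  split_row <- function(l) strsplit(l, "[,\t ]+")[[1L]]
  first <- split_row(lines[1L])
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  if (header) { lines <- lines[-1L]; lnum <- lnum[-1L] }
  if (length(lines) == 0L) stop_validation("no data rows in %s", path)

  fields <- lapply(lines, split_row)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1L]))
    stop_validation("malformed row at line %d of %s: expected %d fields, got %d",
                    lnum[which(ncols != ncols[1L])[1L]], path, ncols[1L],
                    ncols[ncols != ncols[1L]][1L])
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = ncols[1L], byrow = TRUE))
  if (any(is.na(vals))) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop_validation("malformed (non-numeric) row at line %d of %s", lnum[bad], path)
  }

  if (ncols[1L] == 1L) {
    nn <- vals[, 1L]
    if (nn_unit == "seconds") nn <- nn * 1000
    t <- cumsum(nn) / 1000
  } else if (ncols[1L] >= 2L) {
    t <- vals[, 1L]
    nn <- vals[, 2L]
    if (time_unit == "milliseconds") t <- t / 1000
    if (nn_unit == "seconds") nn <- nn * 1000
    if (any(diff(t) <= 0))
      stop_validation("non-increasing timestamps at line %d of %s",
                      lnum[which(diff(t) <= 0)[1L] + 1L], path)
  }
  beat_series(t, nn, subject_id = subject_id)
}

#' Write a beat series as a two-column RR CSV
#'
#' Writes `(t_s, nn_ms)` with a header, 6 decimal places; [read_rr_csv()] on
#' the result reproduces the series.
#'
#' @param series A [beat_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t_s,nn_ms", con)
  writeLines(sprintf("%.6f,%.6f", series$t, series$nn), con)
  invisible(path)
}

#' Write segmented heart-rate data
#'
#' Writes the wearable-style windowed view of a record as CSV with columns
#' `segment_start_s, window_min, mean_hr_bpm, ann_ms, n_beats, coverage`.
#' Values are written with 6 decimal places so a read/write round trip is
#' exact at that precision.
#'
#' @param segments A [segment_hr()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hr_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segmented_hr"))
  s <- segments$segments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("segment_start_s,window_min,mean_hr_bpm,ann_ms,n_beats,coverage", con)
  if (nrow(s) > 0L)
    writeLines(sprintf("%.6f,%.6f,%.6f,%.6f,%d,%.6f",
                       s$start_s, rep(segments$window_min, nrow(s)),
                       s$mean_hr_bpm, s$ann_ms, s$n_beats, s$coverage), con)
  invisible(path)
}

#' Read segmented heart-rate data written by [write_hr_segments()]
#'
#' @param path Path to a segmented-HR CSV.
#' @return A `segmented_hr` object (noise metadata reset: the file carries the
#'   realised HR values, not the generating noise state).
#' @export
read_hr_segments <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  d <- read.table(path, header = TRUE, sep = ",")
  window_min <- if (nrow(d) > 0L) d$window_min[1L] else NA_real_
  seg <- data.frame(start_s = d$segment_start_s, n_beats = as.integer(d$n_beats),
                    ann_ms = d$ann_ms, mean_hr_bpm = d$mean_hr_bpm,
                    coverage = d$coverage)
  seg$ann_clean_ms <- seg$ann_ms
  seg$hr_clean_bpm <- seg$mean_hr_bpm
  new_segmented_hr(seg, window_min = window_min, origin = NA_real_,
                   min_coverage = NA_real_)
}
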