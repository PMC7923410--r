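# End-to-end cohort pipeline: per-window estimator tables, correction
# comparisons, risk-group contrasts and classifier reports, with every seed
# and convention recorded.

#' Pipeline run configuration
#'
#' @param windows_min Window lengths in minutes (default `c(1, 5, 10, 30,
#'   60)`).
#' @param preprocess A [preprocess_config()].
#' @param band_edges Band definitions as in [default_band_edges()].
#' @param noise `"none"`, `"table"` (the PPG error model SD for each window)
#'   or `"custom"`.
#' @param noise_sigma_bpm Noise SD when `noise = "custom"`.
#' @param seed Master seed for every stochastic step.
#' @param feature_window_min Window used for classifier features (default 5).
#' @param apriori_n_freqs Frequency-grid size for the a-priori spectrum.
#' @param classifier_models Models to fit when labels are available.
#' @param nn_configs Random-search budget for the `nn_hr` model.
#' @return A `run_config` list carrying its own FNV-1a hash.
#' @export
run_config <- function(windows_min = c(1, 5, 10, 30, 60),
                       preprocess = preprocess_config(),
                       band_edges = default_band_edges(),
                       noise = c("none", "table", "custom"),
                       noise_sigma_bpm = 0,
                       seed = 1L,
                       feature_window_min = 5,
                       apriori_n_freqs = 1500,
                       classifier_models = c("lr_sdnn24", "lr_sdnnhr24",
                                             "lr_hr", "rf_hr"),
                       nn_configs = 60L) {
  noise <- match.arg(noise)
  if (any(windows_min <= 0)) stop_validation("windows must be positive")
  cfg <- list(windows_min = windows_min, preprocess = preprocess,
              band_edges = band_edges, noise = noise,
              noise_sigma_bpm = noise_sigma_bpm, seed = as.integer(seed),
              feature_window_min = feature_window_min,
              apriori_n_freqs = apriori_n_freqs,
              classifier_models = classifier_models,
              nn_configs = nn_configs)
  cfg$config_hash <- fnv1a_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; the `preprocess` key
#' holds [preprocess_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("preprocess", "band_edges"))]
  if (!is.null(y$preprocess)) args$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$band_edges))
    args$band_edges <- lapply(y$band_edges, as.numeric)
  do.call(run_config, args)
}

# read a cohort directory of per-subject RR CSVs plus an optional sidecar
# labels.csv (subject_id, nyha_class); risk labels are always derived from
# the NYHA class so the class mapping is the single source of truth
read_cohort_dir <- function(cohort_dir, labels_path = file.path(cohort_dir, "labels.csv")) {
  files <- list.files(cohort_dir, pattern = "\\.(csv|txt)$", full.names = TRUE)
  files <- files[basename(files) != "labels.csv"]
  if (length(files) == 0L) stop_validation("no subject files in %s", cohort_dir)
  labels <- NULL
  if (file.exists(labels_path)) {
    labels <- read.table(labels_path, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
  }
  lapply(files, function(f) {
    s <- read_rr_csv(f)
    nyha <- NULL
    if (!is.null(labels)) {
      m <- match(s$subject_id, labels$subject_id)
      if (!is.na(m)) nyha <- labels$nyha_class[m]
    }
    subject_record(s, nyha_class = nyha)
  })
}

#' Run the full analysis pipeline on a cohort
#'
#' Preprocesses every subject, then per window length computes the four
#' time-domain estimators (with optional HR noise), the two spectral
#' corrections against an a-priori cohort spectrum, comparison reports of
#' each HR-derived estimator against SDNN24, risk-group t-scores (when
#' labels are available) and classifier reports. All tables carry the config
#' hash and master seed; reruns with the same inputs are bit-identical.
#'
#' @param cohort Either a directory of per-subject RR CSVs (with optional
#'   `labels.csv` sidecar of `subject_id, nyha_class`) or a list of
#'   [subject_record()]s.
#' @param cfg A [run_config()].
#' @param out_dir Optional directory to write `estimates.csv`,
#'   `comparisons.csv`, `group_tests.csv`, `classification.csv` and
#'   `results.json`.
#' @return A list of tables: `estimates`, `comparisons`, `group_tests`,
#'   `classification`, plus `config_hash`, `seed`, `n_subjects`.
#' @export
run_full_pipeline <- function(cohort, cfg = run_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  if (length(cohort) == 0L) stop_validation("empty cohort")
  stopifnot(all(vapply(cohort, inherits, logical(1), "subject_record")))

  pre <- lapply(cohort, function(rec) {
    cleaned <- preprocess(rec$beat_series, cfg$preprocess)$series
    list(rec = rec, series = cleaned)
  })
  series_list <- lapply(pre, `[[`, "series")
  labels <- vapply(pre, function(x)
    if (is.null(x$rec$risk_label)) NA_character_ else as.character(x$rec$risk_label),
    character(1))
  sdnn_true <- vapply(series_list, sdnn24, numeric(1))

  apriori <- build_apriori_spectrum(series_list, n_freqs = cfg$apriori_n_freqs)

  est_rows <- list(); cmp_rows <- list()
  for (w in cfg$windows_min) {
    sigma <- switch(cfg$noise, none = 0, table = ppg_noise_sigma(w),
                    custom = cfg$noise_sigma_bpm)
    per_subj <- lapply(seq_along(series_list), function(i) {
      est <- sdnn_estimates(series_list[[i]], w, noise_sigma_bpm = sigma,
                            seed = cfg$seed + 1000L * i + round(w))
      var_meas <- est$sdannhr24_ms^2
      est$adj_mean_ms <- adj_mean(var_meas, w, apriori)
      est$adj_w_ms <- adj_w(var_meas, w, apriori)
      est
    })
    tab <- do.call(rbind, per_subj)
    msd <- function(x) sprintf("%.2f +/- %.2f", mean(x), sd(x))
    est_rows[[as.character(w)]] <- data.frame(
      window_min = w,
      sdnn24 = msd(tab$sdnn24_ms), sdnni24 = msd(tab$sdnni24_ms),
      sdann24 = msd(tab$sdann24_ms), sdannhr24 = msd(tab$sdannhr24_ms),
      adj_mean = msd(tab$adj_mean_ms), adj_w = msd(tab$adj_w_ms))
    for (col in c("sdannhr24_ms", "adj_mean_ms", "adj_w_ms")) {
      cr <- compare_estimator(sdnn_true, tab[[col]])
      cmp_rows[[paste(w, col)]] <- data.frame(
        window_min = w, estimator = sub("_ms$", "", col), n = cr$n,
        bias_mean_ms = cr$bias_mean_ms, bias_sd_ms = cr$bias_sd_ms,
        rmse_ms = cr$rmse_ms, pearson_r = cr$pearson_r,
        t_statistic = cr$t_statistic, p_value = cr$p_value)
    }
  }
  estimates <- do.call(rbind, est_rows)
  comparisons <- do.call(rbind, cmp_rows)
  rownames(estimates) <- rownames(comparisons) <- NULL

  group_tests <- NULL
  classification <- NULL
  if (!any(is.na(labels)) && length(unique(labels)) == 2L) {
    gt <- group_ttest(sdnn_true[labels == "low"], sdnn_true[labels == "high"])
    group_tests <- data.frame(feature = "sdnn24", window_min = NA_real_,
                              t_score = gt$t_score, p_value = gt$p_value)
    for (w in cfg$windows_min) {
      shr <- vapply(series_list, function(s) {
        seg <- segment_hr(s, w)
        sdannhr24(seg)
      }, numeric(1))
      gt <- group_ttest(shr[labels == "low"], shr[labels == "high"])
      group_tests <- rbind(group_tests,
        data.frame(feature = "sdannhr24", window_min = w,
                   t_score = gt$t_score, p_value = gt$p_value))
    }

    rows <- build_feature_rows(cohort, window_min = cfg$feature_window_min,
                               seed = cfg$seed)
    if (min(table(rows$label)) < 3L) {
      message("fewer than 3 subjects per class; skipping classifiers")
      reports <- list()
    } else {
    reports <- lapply(cfg$classifier_models, function(m)
      train_classifier(rows, m, split_seed = cfg$seed,
                       nn_configs = cfg$nn_configs))
    reports <- c(reports,
                 list(baseline_classifier(rows, "b1", seed = cfg$seed),
                      baseline_classifier(rows, "b2", seed = cfg$seed)))
    }
    if (length(reports) > 0L) {
      classification <- do.call(rbind, lapply(reports, function(r) {
        m <- r$metrics
        m$model <- r$model
        m
      }))
      rownames(classification) <- NULL
    }
  }

  result <- list(estimates = estimates, comparisons = comparisons,
                 group_tests = group_tests, classification = classification,
                 config_hash = cfg$config_hash, seed = cfg$seed,
                 n_subjects = length(cohort))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv2 <- function(d, f) if (!is.null(d))
      write.table(d, file.path(out_dir, f), sep = ",", row.names = FALSE,
                  quote = FALSE)
    write.csv2(estimates, "estimates.csv")
    write.csv2(comparisons, "comparisons.csv")
    write.csv2(group_tests, "group_tests.csv")
    write.csv2(classification, "classification.csv")
    jsonlite::write_json(result[c("estimates", "comparisons", "group_tests",
                                  "classification", "config_hash", "seed",
                                  "n_subjects")],
                         file.path(out_dir, "results.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  result
}
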