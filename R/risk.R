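# Cardiovascular-risk labelling, HR feature construction, fixed-coefficient
# reference predictors, trainable classifiers and baselines.

#' Map NYHA heart-failure class to a cardiovascular risk label
#'
#' Classes 0-1 (none / mild) map to low risk; classes 2-4 (moderate and
#' severe congestive heart failure) map to high risk.
#'
#' @param nyha_class Integer vector with values in 0-4.
#' @return Factor with levels `low`, `high`.
#' @export
label_risk <- function(nyha_class) {
  if (any(is.na(nyha_class)) || any(nyha_class != round(nyha_class)) ||
      any(nyha_class < 0) || any(nyha_class > 4))
    stop_validation("NYHA class must be an integer in 0..4")
  factor(ifelse(nyha_class >= 2, "high", "low"), levels = c("low", "high"))
}

#' Fixed-coefficient linear predictor of SDNN24 from HR features
#'
#' Evaluates the published regression `SDNN24 = 47.248 + 951.590*SDANNHR24 -
#' 0.347*MESOR` with frozen coefficients. The SDANNHR24 coefficient is only
#' dimensionally sensible with SDANNHR24 in **seconds** (0.1 s contributes
#' ~95 ms); this function therefore takes seconds in and returns
#' milliseconds.
#'
#' @param sdannhr24_s SDANNHR24 in seconds.
#' @param mesor_bpm MESOR in bpm.
#' @return Predicted SDNN24 in ms.
#' @examples
#' predict_sdnn24_fixed(0, 0)      # intercept: 47.248
#' predict_sdnn24_fixed(0.1, 70)   # 118.117
#' @export
predict_sdnn24_fixed <- function(sdannhr24_s, mesor_bpm) {
  stopifnot(all(is.finite(sdannhr24_s)), all(is.finite(mesor_bpm)))
  47.248 + 951.590 * sdannhr24_s - 0.347 * mesor_bpm
}

#' Fixed-coefficient logistic predictor of high cardiovascular risk
#'
#' Evaluates the published logistic discriminant
#' `f(x) = 1 / (1 + exp(0.121 + 0.283*SDANNHR24 - 0.293*MESOR +
#' 0.225*Amplitude))` with frozen coefficients. The coefficient magnitudes
#' (~0.2-0.3) indicate standardised inputs: pass z-scored features. Output
#' increases with MESOR and decreases with SDANNHR24 and amplitude, i.e.
#' higher values indicate higher risk.
#'
#' @param sdannhr24_z,mesor_z,amplitude_z Standardised (z-scored) features.
#' @return Probability in (0, 1).
#' @examples
#' predict_risk_fixed(0, 0, 0)  # 1/(1 + exp(0.121)) ~ 0.4698
#' @export
predict_risk_fixed <- function(sdannhr24_z, mesor_z, amplitude_z) {
  stopifnot(all(is.finite(sdannhr24_z)), all(is.finite(mesor_z)),
            all(is.finite(amplitude_z)))
  eta <- 0.121 + 0.283 * sdannhr24_z - 0.293 * mesor_z + 0.225 * amplitude_z
  1 / (1 + exp(eta))
}

#' Build per-subject HR feature rows from a cohort
#'
#' For each subject computes SDNN24 (ground-truth beat-level), SDANNHR24 at
#' the given window, and the cosinor MESOR and amplitude from the windowed
#' HR, alongside the risk label.
#'
#' @param cohort List of [subject_record()]s with risk labels.
#' @param window_min Window length in minutes (default 5).
#' @param noise_sigma_bpm HR noise SD (default 0); `seed` controls the draw.
#' @param seed Base seed for per-subject noise.
#' @return Data frame with columns `subject_id`, `sdnn24_ms`,
#'   `sdannhr24_ms`, `mesor_bpm`, `amplitude_bpm`, `label`.
#' @export
build_feature_rows <- function(cohort, window_min = 5, noise_sigma_bpm = 0,
                               seed = 1L) {
  stopifnot(all(vapply(cohort, inherits, logical(1), "subject_record")))
  rows <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    s <- rec$beat_series
    seg <- segment_hr(s, window_min)
    if (noise_sigma_bpm > 0)
      seg <- inject_hr_noise(seg, noise_sigma_bpm, seed + i)
    cf <- cosinor_from_segments(seg)
    data.frame(subject_id = s$subject_id,
               sdnn24_ms = sdnn24(s),
               sdannhr24_ms = sdannhr24(seg),
               mesor_bpm = cf$mesor_bpm,
               amplitude_bpm = cf$amplitude_bpm,
               label = if (is.null(rec$risk_label)) NA_character_
                       else as.character(rec$risk_label))
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c("low", "high"))
  out
}

# indices of a stratified sample of `fraction` of each class of y
stratified_take <- function(y, fraction) {
  unlist(lapply(split(seq_along(y), y), function(idx) {
    k <- round(length(idx) * fraction)
    k <- max(1L, min(length(idx) - 1L, k))
    sample(idx, k)
  }), use.names = FALSE)
}

# stratified 70/30 train/test split, deterministic given seed
stratified_split <- function(labels, train_fraction, seed) {
  test_idx <- with_seed(seed, stratified_take(labels, 1 - train_fraction))
  list(train = setdiff(seq_along(labels), test_idx), test = sort(test_idx))
}

#' Per-class precision, recall and F1
#'
#' @param truth,pred Factors (or vectors coercible to character) of true and
#'   predicted classes.
#' @param classes Class levels to report (default: levels of `truth`).
#' @return Data frame with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `support`. Undefined ratios (0/0) are reported as 0.
#' @export
classification_metrics <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(classes)) classes <- unique(sort(truth))
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, precision = precision, recall = recall, f1 = f1,
               support = tp + fn)
  }))
}

new_class_report <- function(metrics, model, split_seed, train_fraction,
                             n_train, n_test, truth, pred, extra = NULL) {
  structure(list(metrics = metrics, model = model, split_seed = split_seed,
                 train_fraction = train_fraction, n_train = n_train,
                 n_test = n_test, test_truth = truth, test_pred = pred,
                 extra = extra),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report> model %s (seed %d, %d train / %d test)\n",
              x$model, x$split_seed, x$n_train, x$n_test))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

.model_features <- list(
  lr_sdnn24 = "sdnn24_ms",
  lr_sdnnhr24 = "sdannhr24_ms",
  lr_hr = c("sdannhr24_ms", "mesor_bpm", "amplitude_bpm"),
  rf_hr = c("sdannhr24_ms", "mesor_bpm", "amplitude_bpm"),
  nn_hr = c("sdannhr24_ms", "mesor_bpm", "amplitude_bpm")
)

#' Train and evaluate a cardiovascular-risk classifier
#'
#' Stratified 70/30 train/test split; features are z-scored on the training
#' split for the logistic and neural models. Models: logistic regression on
#' SDNN24 alone (`lr_sdnn24`), on SDANNHR24 alone (`lr_sdnnhr24`), or on the
#' three HR features SDANNHR24 + MESOR + amplitude (`lr_hr`); a random
#' forest on the HR features (`rf_hr`); and a single-hidden-layer
#' leaky-ReLU/dropout network on the HR features (`nn_hr`), tuned by random
#' search over at most `nn_configs` hyperparameter draws (hidden units 1-8,
#' leaky slope 0-1, dropout 0-0.99, batch size 1-32) on a stratified 80/20
#' train/validation split of the training data. Everything is deterministic
#' given `split_seed`.
#'
#' @param rows Feature data frame from [build_feature_rows()] (or any data
#'   frame with the needed feature columns and a `label` factor).
#' @param model One of `"lr_sdnn24"`, `"lr_sdnnhr24"`, `"lr_hr"`, `"rf_hr"`,
#'   `"nn_hr"`.
#' @param split_seed Integer seed controlling the split (and any model
#'   randomness).
#' @param train_fraction Training fraction (default 0.7).
#' @param nn_configs,nn_epochs Random-search budget and SGD epochs for
#'   `nn_hr` (defaults 400 and 100).
#' @return A `class_report` with per-class precision/recall/F1 on the
#'   held-out 30%.
#' @export
train_classifier <- function(rows, model = c("lr_sdnn24", "lr_sdnnhr24",
                                             "lr_hr", "rf_hr", "nn_hr"),
                             split_seed = 1L, train_fraction = 0.7,
                             nn_configs = 400L, nn_epochs = 100L) {
  model <- match.arg(model)
  feats <- .model_features[[model]]
  if (any(is.na(rows$label))) stop_validation("rows have missing labels")
  if (any(!feats %in% names(rows)))
    stop_validation("missing feature column(s): %s",
                    paste(setdiff(feats, names(rows)), collapse = ", "))
  if (anyNA(rows[feats])) stop_validation("missing values in model features")
  y <- factor(rows$label, levels = c("low", "high"))
  if (any(table(y) < 3L)) stop_validation("need at least 3 subjects per class")

  sp <- stratified_split(y, train_fraction, split_seed)
  xtr <- as.matrix(rows[sp$train, feats, drop = FALSE])
  xte <- as.matrix(rows[sp$test, feats, drop = FALSE])
  ytr <- y[sp$train]; yte <- y[sp$test]
  if (length(unique(ytr)) < 2L) stop_validation("single-class training data")

  if (model %in% c("lr_sdnn24", "lr_sdnnhr24", "lr_hr", "nn_hr")) {
    mu <- colMeans(xtr); sig <- apply(xtr, 2L, sd)
    sig[sig == 0] <- 1
    xtr <- sweep(sweep(xtr, 2L, mu), 2L, sig, `/`)
    xte <- sweep(sweep(xte, 2L, mu), 2L, sig, `/`)
  }

  extra <- NULL
  if (startsWith(model, "lr_")) {
    d <- data.frame(xtr, y = as.integer(ytr == "high"))
    fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
    p <- predict(fit, newdata = data.frame(xte), type = "response")
    pred <- ifelse(p > 0.5, "high", "low")
  } else if (model == "rf_hr") {
    fit <- with_seed(split_seed,
      randomForest::randomForest(x = xtr, y = ytr, ntree = 500))
    pred <- as.character(predict(fit, xte))
  } else {
    rs <- mlp_random_search(xtr, as.integer(ytr == "high"),
                            n_configs = nn_configs, epochs = nn_epochs,
                            seed = split_seed)
    p <- mlp_predict_prob(rs$model, xte)
    pred <- ifelse(p > 0.5, "high", "low")
    extra <- rs$config
  }
  metrics <- classification_metrics(yte, pred, classes = c("low", "high"))
  new_class_report(metrics, model, as.integer(split_seed), train_fraction,
                   length(ytr), length(yte), as.character(yte), pred,
                   extra = extra)
}

#' Baseline classifiers: stratified-random (B1) and majority-class (B2)
#'
#' B1 assigns test labels drawn from the empirical class distribution of the
#' training split; B2 always assigns the training majority class. Both are
#' evaluated on the same stratified 70/30 split as [train_classifier()].
#'
#' @param rows Feature data frame with a `label` column.
#' @param kind `"b1"` or `"b2"`.
#' @param seed Seed for the split and the B1 draw.
#' @param train_fraction Training fraction (default 0.7).
#' @return A `class_report`.
#' @export
baseline_classifier <- function(rows, kind = c("b1", "b2"), seed = 1L,
                                train_fraction = 0.7) {
  kind <- match.arg(kind)
  y <- factor(rows$label, levels = c("low", "high"))
  if (length(y) < 2L) stop_validation("need at least 2 rows")
  sp <- stratified_split(y, train_fraction, seed)
  ytr <- y[sp$train]; yte <- y[sp$test]
  if (kind == "b1") {
    probs <- table(ytr) / length(ytr)
    pred <- with_seed(seed + 1L,
      sample(names(probs), length(yte), replace = TRUE, prob = as.numeric(probs)))
  } else {
    pred <- rep(names(which.max(table(ytr))), length(yte))
  }
  metrics <- classification_metrics(yte, pred, classes = c("low", "high"))
  new_class_report(metrics, paste0("baseline_", kind), as.integer(seed),
                   train_fraction, length(ytr), length(yte),
                   as.character(yte), pred)
}

#' Sample a two-group feature cohort matching published group statistics
#'
#' Draws per-subject feature rows for a low-risk and a high-risk group with
#' SDNN24 distributed N(142.14, 31.05) / N(86.54, 43.29) ms and SDANNHR24
#' (5-min windows) N(128.31, 30.63) / N(64.46, 37.23) ms, correlated with
#' SDNN24 at r = 0.93 (the correlation reported between the two estimators).
#' MESOR and circadian amplitude follow the package's calibration of typical
#' circadian HR parameters: low risk N(72, 8) bpm MESOR and N(8, 3) bpm
#' amplitude; high risk N(80, 10) and N(5, 2.5) (heart-failure patients run
#' higher resting HR with a blunted circadian swing). Draws are truncated to
#' physiological floors (SDNN >= 10 ms, amplitude >= 0.5 bpm, MESOR >= 40).
#'
#' @param n_low,n_high Group sizes.
#' @param seed Integer seed; the cohort is deterministic given it.
#' @return Data frame as from [build_feature_rows()].
#' @export
simulate_feature_cohort <- function(n_low, n_high, seed = 1L) {
  stopifnot(n_low >= 1L, n_high >= 1L)
  with_seed(seed, {
    draw_group <- function(n, lab, sdnn_mu, sdnn_sd, shr_mu, shr_sd,
                           mesor_mu, mesor_sd, amp_mu, amp_sd) {
      z1 <- rnorm(n); z2 <- rnorm(n)
      rho <- 0.93
      sdnn <- pmax(10, sdnn_mu + sdnn_sd * z1)
      shr <- pmax(5, shr_mu + shr_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
      data.frame(
        subject_id = sprintf("%s%03d", lab, seq_len(n)),
        sdnn24_ms = sdnn,
        sdannhr24_ms = shr,
        mesor_bpm = pmax(40, rnorm(n, mesor_mu, mesor_sd)),
        amplitude_bpm = pmax(0.5, rnorm(n, amp_mu, amp_sd)),
        label = lab)
    }
    out <- rbind(
      draw_group(n_low, "low", 142.14, 31.05, 128.31, 30.63, 72, 8, 8, 3),
      draw_group(n_high, "high", 86.54, 43.29, 64.46, 37.23, 80, 10, 5, 2.5))
    out$label <- factor(out$label, levels = c("low", "high"))
    out
  })
}
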