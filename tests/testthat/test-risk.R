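test_that("NYHA classes map to risk labels per the clinical rule", {
  expect_equal(as.character(label_risk(c(0, 1, 2, 3, 4))),
               c("low", "low", "high", "high", "high"))
  expect_error(label_risk(5), "0..4")
  expect_error(label_risk(2.5), "0..4")
})

test_that("the fixed linear SDNN24 predictor evaluates its frozen formula", {
  expect_equal(predict_sdnn24_fixed(0, 0), 47.248)
  expect_equal(predict_sdnn24_fixed(0.1, 70), 47.248 + 95.159 - 24.29,
               tolerance = 1e-10)
  # one extra bpm of MESOR lowers the prediction by 0.347 ms
  expect_equal(predict_sdnn24_fixed(0.1, 71) - predict_sdnn24_fixed(0.1, 70),
               -0.347, tolerance = 1e-10)
})

test_that("the fixed logistic risk predictor evaluates its frozen formula", {
  expect_equal(predict_risk_fixed(0, 0, 0), 1 / (1 + exp(0.121)))
  set.seed(2)
  z <- matrix(rnorm(300), ncol = 3)
  p <- predict_risk_fixed(z[, 1], z[, 2], z[, 3])
  expect_true(all(p > 0 & p < 1))
  # monotone in each argument with the printed coefficient signs
  expect_lt(predict_risk_fixed(1, 0, 0), predict_risk_fixed(0, 0, 0))
  expect_gt(predict_risk_fixed(0, 1, 0), predict_risk_fixed(0, 0, 0))
  expect_lt(predict_risk_fixed(0, 0, 1), predict_risk_fixed(0, 0, 0))
  expect_lt(predict_risk_fixed(50, 0, 0), 1e-5)  # sigmoid limit
})

test_that("classification metrics agree with a direct confusion matrix", {
  set.seed(31)
  truth <- sample(c("low", "high"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.3, "low", truth)
  m <- classification_metrics(truth, pred, classes = c("low", "high"))
  for (cl in c("low", "high")) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    row <- m[m$class == cl, ]
    expect_equal(row$precision, tp / (tp + fp))
    expect_equal(row$recall, tp / (tp + fn))
    expect_equal(row$f1, 2 * row$precision * row$recall /
                   (row$precision + row$recall))
  }
})

test_that("stratified splits preserve class proportions within one subject", {
  rows <- simulate_feature_cohort(35, 25, seed = 3)
  for (seed in 1:5) {
    rep <- train_classifier(rows, "lr_hr", split_seed = seed)
    n_test_high <- sum(rep$test_truth == "high")
    expect_lte(abs(n_test_high - 0.3 * 25), 1)
    expect_lte(abs(rep$n_test - 0.3 * 60), 2)
  }
})

test_that("a linearly separable cohort is classified perfectly", {
  rows <- simulate_feature_cohort(25, 25, seed = 5)
  rows$sdannhr24_ms <- ifelse(rows$label == "high", 40, 160)  # force separation
  rep <- train_classifier(rows, "lr_hr", split_seed = 2)
  expect_equal(metric_of(rep, "high"), 1.0)
  expect_equal(metric_of(rep, "low"), 1.0)
})

test_that("classifier reports are deterministic given the seed", {
  rows <- simulate_feature_cohort(30, 20, seed = 7)
  for (m in c("lr_hr", "rf_hr")) {
    r1 <- train_classifier(rows, m, split_seed = 11)
    r2 <- train_classifier(rows, m, split_seed = 11)
    expect_identical(r1$metrics, r2$metrics)
  }
  n1 <- train_classifier(rows, "nn_hr", split_seed = 11, nn_configs = 6,
                         nn_epochs = 30)
  n2 <- train_classifier(rows, "nn_hr", split_seed = 11, nn_configs = 6,
                         nn_epochs = 30)
  expect_identical(n1$metrics, n2$metrics)
  expect_identical(n1$extra, n2$extra)
})

test_that("the majority baseline zeroes out the minority class", {
  rows <- simulate_feature_cohort(35, 20, seed = 9)
  rep <- baseline_classifier(rows, "b2", seed = 4)
  expect_equal(metric_of(rep, "high", "precision"), 0)
  expect_equal(metric_of(rep, "high", "recall"), 0)
  expect_equal(metric_of(rep, "high"), 0)
  expect_equal(metric_of(rep, "low", "recall"), 1)
  # precision of the constant prediction equals the test-split prevalence
  expect_equal(metric_of(rep, "low", "precision"),
               mean(rep$test_truth == "low"))
})

test_that("the stratified-random baseline attains its closed-form accuracy", {
  rows <- simulate_feature_cohort(35, 20, seed = 2)
  accs <- vapply(1:10000, function(s) {
    rep <- baseline_classifier(rows, "b1", seed = s)
    mean(rep$test_pred == rep$test_truth)
  }, numeric(1))
  # expected accuracy sum p_c^2 under class-distribution-matched guessing
  p <- c(35, 20) / 55
  expect_lt(abs(mean(accs) - sum(p^2)) / sum(p^2), 0.02)
})

test_that("the HR feature set outperforms SDNN24 alone for high-risk F1", {
  wins <- 0; ties <- 0
  for (s in 1:25) {
    rows <- simulate_feature_cohort(35, 25, seed = 100 + s)
    f_hr <- metric_of(train_classifier(rows, "lr_hr", split_seed = s), "high")
    f_sd <- metric_of(train_classifier(rows, "lr_sdnn24", split_seed = s), "high")
    wins <- wins + (f_hr > f_sd)
    ties <- ties + (f_hr == f_sd)
  }
  expect_gt(wins, 25 / 2 - ties)
})
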