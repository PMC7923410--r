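# Estimator-validation statistics: bias, RMSE, Pearson correlation, paired
# and unpaired t-tests with explicit t-score formulas.

#' Compare an estimator against per-subject ground truth
#'
#' Summarises `estimate - truth` as mean +/- SD (sample convention), RMSE,
#' Pearson correlation, and a two-sided paired t-test on the differences.
#'
#' @param truth Numeric vector of ground-truth values (ms).
#' @param estimate Numeric vector of estimates, same length (at least 3).
#' @return A `comparison_report`: `n`, `bias_mean_ms`, `bias_sd_ms`,
#'   `rmse_ms`, `pearson_r` (`NA` if either vector is constant),
#'   `t_statistic`, `p_value`, `test_kind = "paired"`.
#' @examples
#' compare_estimator(c(100, 200, 150), c(110, 190, 155))
#' @export
compare_estimator <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    stop_validation("truth and estimate must have equal length")
  n <- length(truth)
  if (n < 3L) stop_validation("need at least 3 pairs")
  d <- estimate - truth
  bias_mean <- mean(d)
  bias_sd <- sd(d)
  rmse <- sqrt(mean(d^2))
  r <- if (sd(truth) > 0 && sd(estimate) > 0) stats::cor(truth, estimate) else NA_real_
  if (bias_sd > 0) {
    t_stat <- bias_mean / (bias_sd / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1L)
  } else {
    t_stat <- if (bias_mean == 0) 0 else sign(bias_mean) * Inf
    p <- if (bias_mean == 0) 1 else 0
  }
  structure(list(n = n, bias_mean_ms = bias_mean, bias_sd_ms = bias_sd,
                 rmse_ms = rmse, pearson_r = r, t_statistic = t_stat,
                 p_value = p, test_kind = "paired"),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> n=%d: bias %.2f +/- %.2f ms, RMSE %.2f ms, r=%.3f, t=%.2f (p=%.3g)\n",
              x$n, x$bias_mean_ms, x$bias_sd_ms, x$rmse_ms, x$pearson_r,
              x$t_statistic, x$p_value))
  invisible(x)
}

#' Unpaired two-sample t-test with explicit t-score
#'
#' Student's pooled-variance t by default (Welch optional). The t-score's
#' sign is `(mean(group_a) - mean(group_b))/SE`; pass the low-risk group
#' first to follow the healthier-higher-positive convention used when
#' contrasting risk groups.
#'
#' @param group_a,group_b Numeric vectors (each at least 2 values).
#' @param var_equal Pooled-variance Student's t (`TRUE`, default) or Welch.
#' @return A list: `t_score`, `p_value` (two-sided), `df`, `mean_a`,
#'   `mean_b`, `test = "unpaired"`.
#' @export
group_ttest <- function(group_a, group_b, var_equal = TRUE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop_validation("each group needs at least 2 values")
  va <- var(group_a); vb <- var(group_b)
  if (va == 0 && vb == 0 && mean(group_a) != mean(group_b))
    stop_validation("degenerate groups: zero variance with unequal means")
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2L
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  delta <- mean(group_a) - mean(group_b)
  t_score <- if (se > 0) delta / se else 0
  p <- if (se > 0) 2 * pt(-abs(t_score), df = df) else 1
  list(t_score = t_score, p_value = p, df = df,
       mean_a = mean(group_a), mean_b = mean(group_b), test = "unpaired")
}
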