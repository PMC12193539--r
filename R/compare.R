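#' Two-proportion z-test with continuity correction
#'
#' Compares two independent proportions x1/n1 and x2/n2 using the pooled
#' standard error. With `continuity = TRUE` (the default) the absolute
#' difference is reduced by cc = 0.5 (1/n1 + 1/n2) before standardizing;
#' the statistic keeps the sign of p1 - p2 and the p-value is two-sided
#' from the standard normal. The continuity-corrected form is the
#' convention under which the study's printed z values (1.8 and 0.18) are
#' reproduced from counts reconstructed from its percentages.
#'
#' Without the correction, z^2 equals the Pearson chi-square statistic of
#' the corresponding 2x2 table.
#'
#' @param x1,n1 successes and trials of the first sample.
#' @param x2,n2 successes and trials of the second sample.
#' @param continuity apply the continuity correction? Default `TRUE`.
#' @param alpha two-sided rejection probability recorded on the result.
#' @return An object of class `htest` with `statistic` (z), `p.value`,
#'   `estimate` (the two proportions) and `method`.
#' @examples
#' two_proportion_z(22, 26, 8, 15)$statistic  # ~1.81
#' @export
two_proportion_z <- function(x1, n1, x2, n2, continuity = TRUE, alpha = 0.05) {
  for (v in list(x1 = x1, n1 = n1, x2 = x2, n2 = n2)) {
    if (length(v) != 1L || is.na(v) || v < 0) abort("counts must be nonnegative scalars", "usage_error")
  }
  if (x1 > n1 || x2 > n2) abort("successes cannot exceed trials", "usage_error")
  if (n1 == 0 || n2 == 0) abort("sample sizes must be positive", "usage_error")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    abort("degenerate input: pooled proportion is 0 or 1", "degenerate_input_error")
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  cc <- if (continuity) 0.5 * (1 / n1 + 1 / n2) else 0
  num <- max(abs(p1 - p2) - cc, 0)
  z <- sign(p1 - p2) * num / se
  if (p1 == p2) z <- 0
  p_value <- 2 * stats::pnorm(-abs(z))
  structure(list(
    statistic = c(z = z), parameter = NULL, p.value = min(p_value, 1),
    estimate = c(prop1 = p1, prop2 = p2),
    alternative = "two.sided", alpha = alpha,
    method = paste0("two-proportion z-test",
                    if (continuity) " with continuity correction"),
    data.name = sprintf("%g/%g vs %g/%g", x1, n1, x2, n2)
  ), class = "htest")
}

#' Two-sample t-test from summary statistics
#'
#' Compares two group means given only (mean, SEM, n) summaries, as needed
#' when raw durations are unavailable. Sample variances are recovered as
#' s^2 = sem^2 n. `pooled = TRUE` (default, matching the study's printed
#' df = 39 = 26 + 15 - 2) uses the classic pooled-variance statistic with
#' df = n1 + n2 - 2; `pooled = FALSE` uses the Welch statistic
#' (mean1 - mean2) / sqrt(sem1^2 + sem2^2) with Welch-Satterthwaite df.
#'
#' @param mean1,sem1,n1 first group summary (mean, standard error, size).
#' @param mean2,sem2,n2 second group summary.
#' @param pooled pooled-variance (`TRUE`) or Welch (`FALSE`) form.
#' @param alpha two-sided rejection probability recorded on the result.
#' @return An object of class `htest` with `statistic` (t), `parameter`
#'   (df), `p.value` and `method`.
#' @examples
#' two_sample_t_from_summary(387.5, 46.8, 26, 219, 52, 15)$parameter  # df 39
#' @export
two_sample_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                                      pooled = TRUE, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) {
    abort("both samples need n >= 2 for a t-test from summaries", "insufficient_data_error")
  }
  if (sem1 < 0 || sem2 < 0) abort("SEMs must be nonnegative", "usage_error")
  var1 <- sem1^2 * n1
  var2 <- sem2^2 * n2
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    method <- "two-sample t-test from summaries (pooled variance)"
  } else {
    se <- sqrt(sem1^2 + sem2^2)
    df <- (sem1^2 + sem2^2)^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
    method <- "Welch two-sample t-test from summaries"
  }
  if (se == 0) {
    t <- 0
    p_value <- 1
  } else {
    t <- (mean1 - mean2) / se
    p_value <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(
    statistic = c(t = t), parameter = c(df = df), p.value = p_value,
    estimate = c(mean1 = mean1, mean2 = mean2),
    alternative = "two.sided", alpha = alpha, method = method,
    data.name = sprintf("(%g +/- %g, n=%d) vs (%g +/- %g, n=%d)",
                        mean1, sem1, n1, mean2, sem2, n2)
  ), class = "htest")
}

#' Reconstruct an integer count from a printed percentage
#'
#' Returns round(percent x n / 100) with ties rounded away from zero, plus
#' the back-computed percentage for verification against the printed value.
#'
#' @param percent printed percentage in `[0, 100]`.
#' @param n group size.
#' @return List with `count` and `percent_back` (100 x count / n).
#' @examples
#' counts_from_percent(84.6, 26)$count  # 22
#' @export
counts_from_percent <- function(percent, n) {
  if (n <= 0) abort("`n` must be positive", "usage_error")
  if (percent < 0 || percent > 100) abort("`percent` must be in [0, 100]", "usage_error")
  count <- floor(percent * n / 100 + 0.5)  # ties away from zero (inputs nonnegative)
  list(count = as.integer(count), percent_back = 100 * count / n)
}
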