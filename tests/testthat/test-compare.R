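test_that("continuity-corrected z reproduces the published group comparisons", {
  z1 <- two_proportion_z(22, 26, 8, 15)
  expect_equal(round(unname(z1$statistic), 1), 1.8)
  z2 <- two_proportion_z(9, 26, 4, 15)
  expect_equal(round(unname(z2$statistic), 2), 0.18)
  # uncorrected values differ materially, so the correction is load-bearing
  expect_equal(round(unname(two_proportion_z(22, 26, 8, 15, continuity = FALSE)$statistic), 2),
               2.18)

  same <- two_proportion_z(5, 10, 10, 20, continuity = FALSE)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  expect_error(two_proportion_z(0, 10, 0, 15), class = "degenerate_input_error")
  expect_error(two_proportion_z(11, 10, 1, 15), class = "usage_error")
})

test_that("uncorrected z squared equals the 2x2 Pearson chi-square", {
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(5:40, 1)
    n2 <- sample(5:40, 1)
    x1 <- sample(1:(n1 - 1), 1)
    x2 <- sample(1:(n2 - 1), 1)
    z <- unname(two_proportion_z(x1, n1, x2, n2, continuity = FALSE)$statistic)
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-9)
  }
})

test_that("corrected z squared equals the Yates-corrected chi-square", {
  for (xs in list(c(22, 26, 8, 15), c(9, 26, 4, 15), c(12, 30, 20, 28))) {
    z <- unname(two_proportion_z(xs[1], xs[2], xs[3], xs[4])$statistic)
    tab <- matrix(c(xs[1], xs[2] - xs[1], xs[3], xs[4] - xs[3]), 2, byrow = TRUE)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-9)
  }
})

test_that("summary t-test agrees with t.test on raw samples with matching moments", {
  set.seed(17)
  for (i in 1:5) {
    n1 <- sample(5:30, 1)
    n2 <- sample(5:30, 1)
    x <- sample_with_moments(n1, runif(1, 50, 400), runif(1, 5, 60))
    y <- sample_with_moments(n2, runif(1, 50, 400), runif(1, 5, 60))
    sum_t <- two_sample_t_from_summary(mean(x), sd(x) / sqrt(n1), n1,
                                       mean(y), sd(y) / sqrt(n2), n2, pooled = TRUE)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(unname(sum_t$statistic), unname(ref$statistic), tolerance = 1e-9)
    expect_equal(sum_t$p.value, ref$p.value, tolerance = 1e-9)

    sum_w <- two_sample_t_from_summary(mean(x), sd(x) / sqrt(n1), n1,
                                       mean(y), sd(y) / sqrt(n2), n2, pooled = FALSE)
    ref_w <- stats::t.test(x, y, var.equal = FALSE)
    expect_equal(unname(sum_w$statistic), unname(ref_w$statistic), tolerance = 1e-9)
    expect_equal(unname(sum_w$parameter), unname(ref_w$parameter), tolerance = 1e-6)
  }
})

test_that("guarding-duration comparison gives pooled df 39 and p near 0.02", {
  pooled <- two_sample_t_from_summary(387.5, 46.8, 26, 219, 52, 15)
  expect_equal(unname(pooled$parameter), 39)
  welch <- two_sample_t_from_summary(387.5, 46.8, 26, 219, 52, 15, pooled = FALSE)
  expect_equal(round(unname(welch$statistic), 2), 2.41)
  expect_equal(round(welch$p.value, 2), 0.02)

  same <- two_sample_t_from_summary(100, 5, 10, 100, 5, 10)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(two_sample_t_from_summary(10, 0, 1, 12, 1, 5),
               class = "insufficient_data_error")
})

test_that("swapping sample order negates the statistic and preserves p", {
  a <- two_proportion_z(22, 26, 8, 15)
  b <- two_proportion_z(8, 15, 22, 26)
  expect_equal(unname(b$statistic), -unname(a$statistic))
  expect_equal(b$p.value, a$p.value)
  ta <- two_sample_t_from_summary(387.5, 46.8, 26, 219, 52, 15)
  tb <- two_sample_t_from_summary(219, 52, 15, 387.5, 46.8, 26)
  expect_equal(unname(tb$statistic), -unname(ta$statistic))
  expect_equal(tb$p.value, ta$p.value)
})

test_that("counts reconstruct from printed percentages", {
  expect_equal(counts_from_percent(84.6, 26)$count, 22L)
  expect_equal(counts_from_percent(53, 15)$count, 8L)
  expect_equal(counts_from_percent(34, 26)$count, 9L)
  expect_equal(counts_from_percent(26, 15)$count, 4L)
  expect_equal(counts_from_percent(0, 40)$count, 0L)
  expect_equal(counts_from_percent(50, 3)$count, 2L)  # ties away from zero
  expect_error(counts_from_percent(120, 10), class = "usage_error")
})
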