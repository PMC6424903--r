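# Closed-form behavioral statistics: summary t-tests, chi-squared,
# d-prime, exact binomial CIs and the pitch-group classification rule.

test_that("summary t-test matches a brute-force t on raw samples with the same moments", {
  a <- summary_stats(10, 2, 3)
  b <- summary_stats(13, 1.5, 3)
  res <- t_from_summary(a, b)
  raw <- stats::t.test(sample_with_stats(13, 1.5), sample_with_stats(10, 2),
                       var.equal = TRUE)
  expect_equal(res$t, unname(raw$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(raw$parameter))
  expect_equal(res$p, raw$p.value, tolerance = 1e-12)
})

test_that("summary t-test reproduces the published biographical comparisons", {
  # handedness scores
  hand <- t_from_summary(summary_stats(79.43, 23.45, 11),
                         summary_stats(86.75, 10.80, 12))
  expect_printed(hand$t, 0.98)
  expect_printed(hand$d, 0.40)
  expect_equal(hand$df, 21)
  # age at onset of piano practice
  onset <- t_from_summary(summary_stats(6.86, 3.67, 11),
                          summary_stats(7.29, 3.32, 12))
  expect_printed(onset$t, 0.29)
  # years of piano training (sign convention: second group minus first)
  years <- t_from_summary(summary_stats(17.14, 7.87, 11),
                          summary_stats(15.88, 3.86, 12))
  expect_printed(years$t, -0.49)
  # subtle-transgression d-prime comparison
  dp <- t_from_summary(summary_stats(2.28, 1.19, 11),
                       summary_stats(2.22, 1.31, 12))
  expect_printed(dp$t, -0.11)
  expect_printed(dp$d, 0.05)
  # identical summaries give t = 0, d = 0
  same <- t_from_summary(summary_stats(5, 1, 10), summary_stats(5, 1, 10))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  # degenerate variance errors out
  expect_error(t_from_summary(summary_stats(5, 0, 10),
                              summary_stats(5, 0, 10)),
               "pooled variance")
})

test_that("chi-squared independence matches a hand-computed Pearson sum", {
  tab <- matrix(c(3, 8, 6, 6), 2)       # gender by pitch group
  res <- chi2_independence(tab)
  # independent oracle: explicit sum over cells
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_printed(res$chi2, 1.24)
  expect_equal(res$df, 1)
  # secondary-instrument practice table
  res2 <- chi2_independence(matrix(c(9, 2, 7, 5), 2))
  expect_printed(res2$chi2, 1.50)
  # transposition invariance and the no-association case
  expect_equal(chi2_independence(t(tab))$chi2, res$chi2, tolerance = 1e-12)
  expect_equal(chi2_independence(matrix(c(10, 20, 5, 10), 2))$chi2, 0,
               tolerance = 1e-12)
  expect_error(chi2_independence(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("d-prime uses inverse-normal rates with the 1/(2N) extreme correction", {
  expect_equal(dprime(detection_counts(50, 50, 50, 50))$dprime, 0)
  # 84/100 hits vs 16/100 false alarms
  res <- dprime(detection_counts(84, 16, 16, 84))
  expect_equal(res$dprime, stats::qnorm(0.84) - stats::qnorm(0.16),
               tolerance = 1e-12)
  expect_printed(res$dprime, 1.989, digits = 3)
  # perfect performance stays finite through the correction
  perf <- dprime(detection_counts(100, 0, 0, 100))
  expect_true(is.finite(perf$dprime))
  expect_equal(perf$hit_rate, 0.995)
  expect_equal(perf$fa_rate, 0.005)
  # antisymmetry: swapping hits and false alarms negates d'
  a <- dprime(detection_counts(80, 20, 30, 70))
  b <- dprime(detection_counts(30, 70, 80, 20))
  expect_equal(a$dprime, -b$dprime, tolerance = 1e-12)
})

test_that("Clopper-Pearson interval matches the Beta-quantile closed form", {
  expect_equal(binomial_ci(0, 20)[["lower"]], 0)
  expect_equal(binomial_ci(20, 20)[["upper"]], 1)
  ci <- binomial_ci(13, 108)
  expect_equal(ci[["upper"]], stats::qbeta(0.975, 14, 95), tolerance = 1e-12)
  expect_printed(ci[["upper"]], 0.198, digits = 3)
  # cross-check against the exact binomial test
  bt <- stats::binom.test(13, 108)$conf.int
  expect_equal(unname(ci), c(bt[1], bt[2]), tolerance = 1e-9)
})

test_that("pitch-group classification applies the CI inclusion rules", {
  expect_identical(classify_pitch_group(107, 108), "AP")
  expect_gte(binomial_ci(107, 108)[["lower"]], 0.90)
  expect_identical(classify_pitch_group(13, 108), "NAP")
  expect_identical(classify_pitch_group(75, 108), "excluded")
})

test_that("musical-test scoring tabulates hits and shared false alarms per level", {
  n <- 90
  resp <- data.frame(
    condition = rep(c("R", "Tsub", "Tapp"), each = n),
    judgment = rep(c("appropriate", "not_appropriate", "not_appropriate"),
                   each = n))
  sc <- score_musical_test(resp)
  expect_equal(sc$Tsub$counts$hits, n)
  expect_equal(sc$Tsub$counts$false_alarms, 0)
  expect_true(all(is.finite(sc$dprime)))
  # a rater with known hit/fa probabilities converges on z(h) - z(f)
  set.seed(11)
  dps <- replicate(500, {
    r <- data.frame(
      condition = rep(c("R", "Tsub", "Tapp"), each = n),
      judgment = ifelse(stats::runif(3 * n) <
                          rep(c(0.1, 0.9, 0.9), each = n),
                        "not_appropriate", "appropriate"))
    score_musical_test(r)$Tsub$dprime
  })
  expected <- stats::qnorm(0.9) - stats::qnorm(0.1)
  expect_lt(abs(mean(dps) - expected),
            3 * stats::sd(dps) / sqrt(length(dps)) + 0.05)
  # a coin-flipping rater has d-prime near zero on average
  set.seed(12)
  dp0 <- replicate(300, {
    r <- data.frame(
      condition = rep(c("R", "Tsub", "Tapp"), each = n),
      judgment = sample(c("appropriate", "not_appropriate"), 3 * n,
                        replace = TRUE))
    score_musical_test(r)$Tsub$dprime
  })
  expect_lt(abs(mean(dp0)), 0.05)
  expect_error(score_musical_test(data.frame(condition = "R",
                                             judgment = "appropriate")),
               "conditions")
})
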