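#' Group summary statistics
#'
#' @param mean group mean
#' @param sd group standard deviation (>= 0)
#' @param n group size (>= 2)
#' @return an object of class `summary_stats`
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Student t-test from group summaries
#'
#' Pooled-variance independent-sample t-test computed directly from printed
#' group means, SDs and sizes; `t = (mean_b - mean_a) / SE` (second group
#' minus first), `df = n_a + n_b - 2`, two-sided p, and Cohen's
#' `d = |mean difference| / pooled SD`.
#'
#' @param a,b [summary_stats] for the two groups
#' @return list `(t, df, p, d, mean_a, sd_a, mean_b, sd_b)`
#' @export
t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 <= 0) stop("zero pooled variance: t undefined", call. = FALSE)
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  tval <- (b$mean - a$mean) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       d = abs(b$mean - a$mean) / sqrt(sp2),
       mean_a = a$mean, sd_a = a$sd, mean_b = b$mean, sd_b = b$sd)
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction; `df = (r - 1) * (c - 1)`.
#'
#' @param table 2-D matrix of counts with positive marginals
#' @return list `(chi2, df, p)`
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-squared test needs positive marginals", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Detection counts for a yes/no discrimination task
#'
#' @param hits,misses signal-trial outcomes (correctly / incorrectly judged)
#' @param false_alarms,correct_rejections noise-trial outcomes
#' @return object of class `detection_counts`
#' @export
detection_counts <- function(hits, misses, false_alarms, correct_rejections) {
  vals <- c(hits, misses, false_alarms, correct_rejections)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("detection counts must be non-negative integers", call. = FALSE)
  }
  if (hits + misses < 1 || false_alarms + correct_rejections < 1) {
    stop("both signal and noise trials are required", call. = FALSE)
  }
  structure(list(hits = hits, misses = misses, false_alarms = false_alarms,
                 correct_rejections = correct_rejections),
            class = "detection_counts")
}

#' Sensitivity index d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with the standard-normal
#' quantile; rates of exactly 0 or 1 are first adjusted by the `1/(2N)` rule
#' (0 becomes `1/(2N)`, 1 becomes `1 - 1/(2N)`), so the result is always
#' finite.
#'
#' @param counts a [detection_counts]
#' @return list `(dprime, hit_rate, fa_rate)` (rates after correction)
#' @export
dprime <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  n_sig <- counts$hits + counts$misses
  n_noise <- counts$false_alarms + counts$correct_rejections
  adjust <- function(k, n) {
    r <- k / n
    if (r == 0) r <- 1 / (2 * n)
    if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  hr <- adjust(counts$hits, n_sig)
  fr <- adjust(counts$false_alarms, n_noise)
  list(dprime = stats::qnorm(hr) - stats::qnorm(fr),
       hit_rate = hr, fa_rate = fr)
}

#' Exact binomial confidence interval
#'
#' Clopper-Pearson interval via Beta quantiles (the default and currently
#' only method).
#'
#' @param k successes (0..n)
#' @param n trials (>= 1)
#' @param level confidence level (default 0.95)
#' @param method interval type, only `"clopper-pearson"`
#' @return numeric `c(lower, upper)`
#' @export
binomial_ci <- function(k, n, level = 0.95, method = "clopper-pearson") {
  stopifnot(n >= 1, k >= 0, k <= n)
  method <- match.arg(method)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Classify a pitch-naming score into the study groups
#'
#' On the 108-tone naming test, a participant is a true absolute-pitch
#' possessor (`AP`) iff the lower bound of the exact 95 percent CI of the
#' accuracy is at least 0.90; a non-possessor (`NAP`) iff the upper bound is
#' at most 0.65; anything in between is excluded.
#'
#' @param k correct answers
#' @param n total tones presented (default 108)
#' @param level confidence level
#' @return `"AP"`, `"NAP"`, or `"excluded"`
#' @export
classify_pitch_group <- function(k, n = 108, level = 0.95) {
  ci <- binomial_ci(k, n, level)
  if (ci[["lower"]] >= 0.90) return("AP")
  if (ci[["upper"]] <= 0.65) return("NAP")
  "excluded"
}

#' Score the harmonic-transgression judgment task
#'
#' Responses are tabulated into detection counts per transgression level:
#' hits are "not appropriate" judgments of transgressed endings (`Tsub`
#' subtle, `Tapp` apparent) and false alarms are "not appropriate" judgments
#' of regular endings (`R`), shared between the two levels.  d-prime is
#' computed per level.
#'
#' @param responses data frame with columns `condition`
#'   (`"R"`, `"Tsub"`, `"Tapp"`) and `judgment`
#'   (`"appropriate"` or `"not_appropriate"`)
#' @return list with per-level [detection_counts] and a `dprime` table
#' @export
score_musical_test <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("condition", "judgment") %in% names(responses)))
  need <- c("R", "Tsub", "Tapp")
  if (!all(need %in% responses$condition)) {
    stop("responses must include conditions R, Tsub and Tapp", call. = FALSE)
  }
  notappr <- responses$judgment == "not_appropriate"
  n_r <- sum(responses$condition == "R")
  fa <- sum(notappr & responses$condition == "R")
  out <- lapply(c(Tsub = "Tsub", Tapp = "Tapp"), function(cond) {
    n_sig <- sum(responses$condition == cond)
    h <- sum(notappr & responses$condition == cond)
    counts <- detection_counts(h, n_sig - h, fa, n_r - fa)
    c(counts = list(counts), dprime(counts))
  })
  list(Tsub = out$Tsub, Tapp = out$Tapp,
       dprime = c(Tsub = out$Tsub$dprime, Tapp = out$Tapp$dprime))
}
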