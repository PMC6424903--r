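# Microstate segmentation, map grouping, duration smoothing, model
# selection, back-fitting and the nonparametric group comparison.

# Build an ERP whose maps cycle through the given templates in blocks.
erp_from_templates <- function(templates, block_len, n_blocks, srate = 250,
                               gfp_scale = NULL) {
  q <- nrow(templates)
  seqs <- rep(rep(seq_len(q), each = block_len), length.out = n_blocks *
                block_len)
  if (is.null(gfp_scale)) gfp_scale <- rep(1, length(seqs))
  maps <- t(templates[seqs, , drop = FALSE]) *
    rep(gfp_scale, each = ncol(templates))
  erp(maps, srate = srate, t0_index = 1)
}

orthonormal_maps <- function(q, channels, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(channels * q), channels, q)
  m <- sweep(m, 2, colMeans(m))          # average-referenced
  q <- qr.Q(qr(m))[, seq_len(q), drop = FALSE]
  q <- sweep(q, 2, colMeans(q))
  t(apply(t(q), 1, function(v) v / sqrt(sum(v^2))))
}

test_that("segmentation perfectly fits single-map and orthogonal two-map data", {
  tpl <- orthonormal_maps(2, 16)
  # one fixed map under arbitrary positive scaling: q = 1 explains it all
  x1 <- erp_from_templates(tpl[1, , drop = FALSE], 5, 8,
                           gfp_scale = stats::runif(40, 0.5, 3))
  m1 <- segment_microstates(x1, window_ms = c(0, 150), q_range = 1,
                            n_restarts = 10, seed = 2)[[1]]
  expect_equal(m1$gev_total, 1, tolerance = 1e-12)
  # two orthogonal maps in alternating blocks: both recovered with |r| = 1
  x2 <- erp_from_templates(tpl, 10, 6)
  m2 <- segment_microstates(x2, window_ms = c(0, 230), q_range = 2,
                            n_restarts = 20, seed = 2)[[1]]
  expect_equal(m2$gev_total, 1, tolerance = 1e-10)
  r <- abs(m2$templates %*% t(tpl))
  expect_equal(sort(apply(r, 1, max)), c(1, 1), tolerance = 1e-8)
})

test_that("GEV of the best segmentation is non-decreasing in q", {
  lf <- fix_leadfield()
  spec <- sim_spec(n_ap = 2, n_nap = 2, epochs_per_condition = 6,
                   srate = 256, artifact_rate = 0, seed = 4)
  ga <- lapply(c("AP", "NAP"), function(g) {
    erps <- lapply(1:2, function(i) {
      conds <- simulate_subject(spec, g, lf, i)
      collapse_conditions(lapply(conds, average_epochs))
    })
    collapse_conditions(erps)
  })
  models <- segment_microstates(ga, q_range = 1:5, n_restarts = 30, seed = 9)
  gev <- vapply(models, `[[`, numeric(1), "gev_total")
  expect_true(all(diff(gev) >= -1e-9))
})

test_that("map grouping merges by the squared-correlation threshold", {
  tpl <- orthonormal_maps(2, 16)
  x <- erp_from_templates(tpl, 10, 6)
  m <- segment_microstates(x, window_ms = c(0, 230), q_range = 2,
                           n_restarts = 20, seed = 2)[[1]]
  # orthogonal templates are untouched
  expect_equal(merge_similar_maps(m)$q, 2)
  # near-identical templates merge down to one
  m_dup <- m
  m_dup$templates <- m$templates[c(1, 1), ]
  expect_equal(merge_similar_maps(m_dup)$q, 1)
  # threshold boundary: r^2 = 0.93 merges, r^2 = 0.91 does not
  mix <- function(r2) {
    a <- tpl[1, ]
    b <- sqrt(r2) * tpl[1, ] + sqrt(1 - r2) * tpl[2, ]
    rbind(a, b / sqrt(sum(b^2)))
  }
  m93 <- m; m93$templates <- mix(0.93)
  expect_equal(merge_similar_maps(m93)$q, 1)
  m91 <- m; m91$templates <- mix(0.91)
  expect_equal(merge_similar_maps(m91)$q, 2)
})

test_that("sub-minimum segments dissolve into their better neighbors", {
  tpl <- orthonormal_maps(3, 16)
  srate <- 250                              # 4 ms per sample
  labels <- c(rep(1L, 10), rep(2L, 1), rep(3L, 10))
  maps <- t(tpl[labels, ])
  m <- new_model_for_test(maps, tpl, labels, srate)
  sm <- enforce_min_duration(m, 20)
  runs <- rle(sm$labels)
  expect_true(all(runs$lengths * 1000 / srate >= 20))
  expect_false(2L %in% sm$labels)           # the 4 ms island is absorbed
  # already-compliant labelings are unchanged
  ok <- c(rep(1L, 10), rep(2L, 10))
  m2 <- new_model_for_test(t(tpl[ok, ]), tpl, ok, srate)
  expect_identical(enforce_min_duration(m2, 20)$labels, ok)
  # worst case: alternating single-sample labels collapse to one segment
  alt <- rep(c(1L, 2L), 12)
  m3 <- new_model_for_test(t(tpl[alt, ]), tpl, alt, srate)
  expect_equal(length(unique(enforce_min_duration(m3, 20)$labels)), 1)
  expect_error(enforce_min_duration(m2, 500), "shorter")
})

test_that("model selection finds planted q and falls back gracefully", {
  tpl <- orthonormal_maps(3, 20, seed = 8)
  set.seed(8)
  x <- erp_from_templates(tpl, 12, 6,
                          gfp_scale = stats::runif(72, 0.8, 2))
  models <- segment_microstates(x, window_ms = c(0, 280), q_range = 1:6,
                                n_restarts = 30, seed = 3)
  sel <- select_microstate_model(models)
  expect_equal(sel$q, 3)
  # single candidate short-circuits
  expect_equal(select_microstate_model(models["q1"])$q, 1)
  # white-noise data: no dominant KL peak forces the CV fallback
  set.seed(14)
  noise <- erp(matrix(stats::rnorm(20 * 60), 20, 60), 250, 1)
  nm <- segment_microstates(noise, window_ms = c(0, 230), q_range = 1:5,
                            n_restarts = 20, seed = 4)
  ns <- select_microstate_model(nm)
  expect_true(ns$q %in% 1:5)
  expect_true(is.character(ns$reason))
})

test_that("back-fitting is self-consistent and label-scale-invariant", {
  tpl <- orthonormal_maps(2, 16)
  x <- erp_from_templates(tpl, 10, 6, gfp_scale = stats::runif(60, 0.5, 2))
  m <- segment_microstates(x, window_ms = c(0, 230), q_range = 2,
                           n_restarts = 20, seed = 2)[[1]]
  fit <- fit_templates(m, x, window_ms = c(0, 230))
  # total fitted GEV equals the segmentation GEV
  expect_equal(sum(fit$gev_pct) / 100, m$gev_total, tolerance = 1e-9)
  # durations tile the fitted window (59 samples at 4 ms)
  n_win <- length(erpmicro:::window_to_indices(c(0, 230), 250, 1, 60))
  expect_equal(sum(fit$duration_ms), n_win * 1000 / 250)
  # scaling the ERP leaves labels and GEV percentages unchanged
  x2 <- x; x2$data <- x2$data * 7
  expect_equal(fit_templates(m, x2, c(0, 230))$gev_pct, fit$gev_pct,
               tolerance = 1e-9)
  # a single template owns the full window
  one <- fit_templates(m$templates[1, , drop = FALSE], x, c(0, 230))
  expect_equal(one$duration_ms, n_win * 4)
})

test_that("Kruskal-Wallis comparison matches brute-force rank computation", {
  brute_H <- function(a, b) {
    x <- c(a, b); g <- rep(1:2, c(length(a), length(b)))
    r <- rank(x); N <- length(x)
    H <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  res <- compare_groups_param(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$H, brute_H(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(round(res$H, 3), 3.857)
  res2 <- compare_groups_param(c(1, 2), c(3, 4))
  expect_equal(res2$H, 2.4, tolerance = 1e-12)
  # identical distributions across groups stay unremarkable
  res3 <- compare_groups_param(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_lt(res3$H, 1e-12)
  expect_gt(res3$p, 0.05)
  expect_warning(same <- compare_groups_param(c(2, 2), c(2, 2)),
                 "identical")
  expect_equal(same$H, 0)
})
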