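# Spherical head model, solution grid, analytic lead field, and the
# depth-weighted minimum-norm inverse.

test_that("head model validates geometry and conductivities", {
  expect_error(head_model(radii = c(0.1, 0.09, 0.11)), "increasing")
  expect_error(head_model(conductivities = c(0.3, 0, 0.3)), "> 0")
  hm <- head_model(scalp_radius = 0.092)
  expect_equal(hm$radii[3], 0.092)
  expect_equal(hm$radii[1] / hm$radii[3], 0.87, tolerance = 1e-12)
})

test_that("shell transfer reduces to the single-sphere closed form", {
  hm_eq <- head_model(conductivities = c(0.33, 0.33, 0.33))
  Tn <- erpmicro:::shell_transfer(hm_eq, 150)
  n <- seq_len(150)
  expect_equal(Tn, (2 * n + 1) / n, tolerance = 1e-12)
  # skull attenuation damps high degrees below the single-sphere values
  Tn3 <- erpmicro:::shell_transfer(head_model(), 150)
  expect_true(all(Tn3[10:150] < Tn[10:150]))
  expect_true(all(is.finite(Tn3)))
})

test_that("the primary Legendre expansion equals the free-space dipole potential", {
  # independent oracle: Phi = m . (r - r0) / (4 pi sigma |r - r0|^3)
  set.seed(42)
  R <- 0.1; sigma <- 0.33
  for (trial in 1:6) {
    p <- stats::runif(3, -0.04, 0.04)
    m <- stats::rnorm(3)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    b <- sqrt(sum(p^2)); zhat <- p / b
    cth <- sum(u * zhat)
    ab <- erpmicro:::series_alpha_beta(rep(1, 300), b / R, cth, 1e-14)
    v_series <- ((ab$alpha - ab$beta * cth) * sum(m * zhat) +
                   ab$beta * sum(m * u)) / (4 * pi * sigma * R^2)
    re <- u * R - p
    v_direct <- sum(m * re) / (4 * pi * sigma * sum(re^2)^1.5)
    expect_equal(v_series, v_direct, tolerance = 1e-10)
  }
})

test_that("solution grid matches brute-force lattice enumeration", {
  hm <- fix_headmodel()
  g <- build_solution_grid(hm, spacing = 0.040)
  # independent triple-loop count of lattice points inside the sphere
  cnt <- 0
  for (i in -3:3) for (j in -3:3) for (k in -3:3) {
    if ((i^2 + j^2 + k^2) * 0.040^2 < hm$radii[1]^2) cnt <- cnt + 1
  }
  expect_equal(nrow(g$nodes), cnt)
  # origin node present; all nodes strictly inside the brain shell
  expect_true(any(rowSums(g$nodes^2) == 0))
  expect_true(all(sqrt(rowSums(g$nodes^2)) < hm$radii[1]))
  # adjacency is symmetric
  expect_true(Matrix::isSymmetric(g$adjacency))
  expect_error(build_solution_grid(hm, spacing = 0.5), "empty")
})

test_that("target-count spacing is optimal over a spacing scan", {
  hm <- fix_headmodel()
  g <- fix_grid()
  achieved <- abs(nrow(g$nodes) - 1000)
  count_for <- function(s) {
    k <- floor(hm$radii[1] / s)
    ax <- (-k:k) * s
    gr <- expand.grid(ax, ax, ax)
    sum(gr[[1]]^2 + gr[[2]]^2 + gr[[3]]^2 < hm$radii[1]^2)
  }
  scan <- vapply(seq(0.010, 0.020, by = 0.0002), count_for, numeric(1))
  expect_lte(achieved, min(abs(scan - 1000)))
})

test_that("lead field is average-referenced, linear and rotation-invariant", {
  lf <- fix_leadfield()
  expect_lt(max(abs(colSums(lf$matrix))) / max(abs(lf$matrix)), 1e-10)
  # linearity: doubling the moment doubles the potentials
  m <- c(0.3, -1, 2)
  v1 <- lf$matrix[, 1:3] %*% m
  v2 <- lf$matrix[, 1:3] %*% (2 * m)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  # rotating dipole, moment and electrodes together leaves potentials fixed
  hm <- fix_headmodel()
  mon <- fix_montage()
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  one_node_grid <- function(p) {
    g <- fix_grid()
    g$nodes <- matrix(p, 1)
    g$adjacency <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        dims = c(1, 1))
    g
  }
  p <- c(0.03, 0.02, 0.04)
  mon_rot <- montage(mon$labels, mon$positions %*% t(Rz), mon$scalp_radius)
  v <- compute_leadfield(mon, one_node_grid(p), hm)$matrix %*% m
  v_rot <- compute_leadfield(mon_rot, one_node_grid(as.numeric(Rz %*% p)),
                             hm)$matrix %*% as.numeric(Rz %*% m)
  expect_equal(v, v_rot, tolerance = 1e-8 * max(abs(v)))
})

test_that("lead-field strength decays with depth along a radius", {
  lf <- fix_leadfield()
  g <- fix_grid()
  zline <- which(abs(g$nodes[, 1]) < 1e-12 & abs(g$nodes[, 2]) < 1e-12 &
                   g$nodes[, 3] >= 0)
  zline <- zline[order(g$nodes[zline, 3])]
  norms <- vapply(zline, function(v)
    sqrt(sum(lf$matrix[, 3 * (v - 1) + 1:3]^2)), numeric(1))
  expect_true(all(diff(norms) > 0))
})

test_that("WMN inverse is linear, reduces at gamma 0, and localizes when standardized", {
  lf <- fix_leadfield()
  inv <- fix_inverse()
  # zero data give a zero estimate
  expect_equal(as.numeric(inv$matrix %*% numeric(64)),
               numeric(nrow(inv$matrix)))
  # gamma = 0 equals the unweighted minimum norm
  lam <- inv$lambda
  inv0 <- build_inverse_operator(lf, lambda = lam, gamma = 0)
  L <- lf$matrix
  G_ref <- t(L) %*% solve(L %*% t(L) + lam * diag(64))
  expect_lt(max(abs(inv0$matrix - G_ref)), 1e-12 * max(abs(G_ref)))
  # activity scales with the data (norm homogeneity)
  g <- fix_grid()
  x <- erp(matrix(stats::rnorm(64 * 30), 64, 30), 256, 10)
  a1 <- apply_inverse(x, inv, c(20, 60))
  x2 <- x; x2$data <- 2 * x$data
  expect_equal(apply_inverse(x2, inv, c(20, 60)), 2 * a1, tolerance = 1e-12)
  zero <- erp(matrix(0, 64, 30), 256, 10)
  expect_equal(apply_inverse(zero, inv, c(20, 60)),
               numeric(nrow(g$nodes)))
  expect_error(apply_inverse(x, inv, c(-500, 0)), "outside")
})

test_that("standardized unweighted inverse localizes noiseless dipoles exactly", {
  # forward-then-inverse sweep over 20 random interior nodes
  lf <- fix_leadfield()
  g <- fix_grid()
  # lambda -> small: a tiny fraction of the default SNR-based value
  lam0 <- build_inverse_operator(lf, gamma = 0)$lambda
  inv0 <- build_inverse_operator(lf, lambda = lam0 * 1e-6, gamma = 0)
  r_node <- sqrt(rowSums(g$nodes^2))
  interior <- which(r_node < g$r_brain - g$spacing)
  set.seed(7)
  nodes <- sample(interior, 20)
  errs <- vapply(nodes, function(v) {
    ori <- stats::rnorm(3); ori <- ori / sqrt(sum(ori^2))
    u <- as.numeric(lf$matrix[, 3 * (v - 1) + 1:3] %*% ori)
    x <- erp(matrix(u, 64, 1), 256, 1)
    act <- apply_inverse(x, inv0, c(0, 0), standardized = TRUE)
    sqrt(sum((g$nodes[which.max(act), ] - g$nodes[v, ])^2)) / g$spacing
  }, numeric(1))
  expect_gte(mean(errs <= 1 + 1e-9), 0.95)
})
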