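#' Three-shell spherical head model
#'
#' Concentric brain / skull / scalp spheres with homogeneous isotropic
#' conductivities.  Default relative radii 0.087 / 0.092 / 0.100 and
#' conductivities 0.33 / 0.0042 / 0.33 S/m are the conventional three-shell
#' values; `scalp_radius` rescales the whole geometry so the outer shell
#' matches the montage sphere.
#'
#' @param radii shell radii in meters, strictly increasing
#'   (brain, skull, scalp)
#' @param conductivities shell conductivities in S/m, all positive
#' @param scalp_radius if given, radii are rescaled so
#'   `radii[3] == scalp_radius`
#' @param tol relative truncation tolerance of the Legendre series
#' @param n_max maximum series degree
#' @return an object of class `head_model`
#' @export
head_model <- function(radii = c(0.087, 0.092, 0.100),
                       conductivities = c(0.33, 0.0042, 0.33),
                       scalp_radius = NULL, tol = 1e-10, n_max = 300L) {
  stopifnot(length(radii) == 3, length(conductivities) == 3)
  if (!is.null(scalp_radius)) radii <- radii * (scalp_radius / radii[3])
  if (any(diff(radii) <= 0)) stop("shell radii must be strictly increasing",
                                  call. = FALSE)
  if (any(conductivities <= 0)) stop("conductivities must be > 0",
                                     call. = FALSE)
  structure(list(radii = radii, conductivities = conductivities,
                 tol = tol, n_max = as.integer(n_max)),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> radii %s m, sigma %s S/m\n",
              paste(signif(x$radii, 4), collapse = "/"),
              paste(signif(x$conductivities, 4), collapse = "/")))
  invisible(x)
}

# Radial transfer coefficients of the concentric three-sphere problem.
# For each harmonic degree n the potential in shell j is
# A_j x^n + B_j x^(-(n+1)) (x = r / scalp radius); the dipole's primary
# expansion in the innermost shell supplies a known x^(-(n+1)) coefficient S.
# Continuity of potential and of sigma * dPhi/dx at the two interfaces and a
# no-flux condition at the scalp give a 5x5 linear system; the transfer
# T_n = (A_3 + B_3) / S maps S to the scalp-surface potential coefficient.
# For equal conductivities this reduces to the single-sphere (2n+1)/n.
shell_transfer <- function(hm, n_max) {
  R <- hm$radii[3]
  x1 <- hm$radii[1] / R
  x2 <- hm$radii[2] / R
  s <- hm$conductivities
  vapply(seq_len(n_max), function(n) {
    # unknowns: A1, A2, B2, A3, B3
    M <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # potential continuity at x1: A1 x1^n + S x1^-(n+1) = A2 x1^n + B2 x1^-(n+1)
    M[1, ] <- c(x1^n, -x1^n, -x1^(-(n + 1)), 0, 0)
    rhs[1] <- -x1^(-(n + 1))
    # flux continuity at x1
    M[2, ] <- c(s[1] * n * x1^(n - 1),
                -s[2] * n * x1^(n - 1),
                s[2] * (n + 1) * x1^(-(n + 2)), 0, 0)
    rhs[2] <- s[1] * (n + 1) * x1^(-(n + 2))
    # potential continuity at x2
    M[3, ] <- c(0, x2^n, x2^(-(n + 1)), -x2^n, -x2^(-(n + 1)))
    # flux continuity at x2
    M[4, ] <- c(0, s[2] * n * x2^(n - 1), -s[2] * (n + 1) * x2^(-(n + 2)),
                -s[3] * n * x2^(n - 1), s[3] * (n + 1) * x2^(-(n + 2)))
    # insulating scalp surface at x = 1
    M[5, ] <- c(0, 0, 0, n, -(n + 1))
    # equilibrate: x^n vs x^-(n+1) terms span many orders at large n
    cs <- apply(abs(M), 2, max)
    Ms <- sweep(M, 2, cs, "/")
    rs <- apply(abs(Ms), 1, max)
    sol <- solve(Ms / rs, rhs / rs) / cs
    sol[4] + sol[5]                # A3 + B3 at x = 1
  }, numeric(1))
}

#' Build a cubic solution grid inside the brain shell
#'
#' Nodes are the points of a cubic lattice centered at the origin that fall
#' strictly inside the brain sphere.  Either `spacing` (meters) or
#' `target_count` must be given; with `target_count` the spacing is solved by
#' bisection to the lattice whose node count is nearest the target.
#' Adjacency connects node pairs within `connection_radius`; the default
#' (`NULL`) is 10 mm, widened to the lattice spacing on grids coarser than
#' 10 mm so that the face-neighbor structure is always retained.
#'
#' @param headmodel a [head_model]
#' @param spacing lattice spacing in meters
#' @param target_count desired number of nodes (e.g. 3005)
#' @param connection_radius adjacency radius in meters, or `NULL` for
#'   `max(0.010, spacing)`
#' @return an object of class `solution_grid` with fields `nodes` (N x 3,
#'   meters), `spacing`, `r_brain`, `adjacency` (sparse symmetric logical)
#' @export
build_solution_grid <- function(headmodel, spacing = NULL,
                                target_count = NULL,
                                connection_radius = NULL) {
  stopifnot(inherits(headmodel, "head_model"))
  r_brain <- headmodel$radii[1]
  count_for <- function(s) {
    k <- floor(r_brain / s)
    if (k < 0) return(0L)
    ax <- (-k:k) * s
    g <- expand.grid(x = ax, y = ax, z = ax)
    sum(g$x^2 + g$y^2 + g$z^2 < r_brain^2)
  }
  if (is.null(spacing)) {
    if (is.null(target_count) || target_count < 8) {
      stop("give spacing > 0 or target_count >= 8", call. = FALSE)
    }
    lo <- r_brain / (ceiling(target_count^(1 / 3)) + 2)   # too many nodes
    hi <- 2 * r_brain                                     # too few
    best <- NULL
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      cnt <- count_for(mid)
      if (is.null(best) || abs(cnt - target_count) < abs(best$cnt - target_count)) {
        best <- list(s = mid, cnt = cnt)
      }
      if (cnt > target_count) lo <- mid else hi <- mid
    }
    spacing <- best$s
  }
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (spacing > 2 * r_brain) {
    stop("spacing larger than the brain diameter yields an empty grid",
         call. = FALSE)
  }
  k <- floor(r_brain / spacing)
  if (is.null(connection_radius)) {
    connection_radius <- max(0.010, spacing * (1 + 1e-9))
  }
  ax <- -k:k
  g <- as.matrix(expand.grid(i = ax, j = ax, k = ax))
  keep <- (g[, 1]^2 + g[, 2]^2 + g[, 3]^2) * spacing^2 < r_brain^2
  ik <- g[keep, , drop = FALSE]
  nodes <- ik * spacing
  n <- nrow(nodes)
  # adjacency via integer lattice offsets within the connection radius
  max_off <- floor(connection_radius / spacing)
  offs <- as.matrix(expand.grid(-max_off:max_off, -max_off:max_off,
                                -max_off:max_off))
  offs <- offs[rowSums(offs^2) * spacing^2 <= connection_radius^2 + 1e-12, ,
               drop = FALSE]
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ,
               drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx <- seq_len(n)
  names(idx) <- key(ik)
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(nrow(offs))) {
    shifted <- sweep(ik, 2, offs[r, ], "+")
    hit <- idx[key(shifted)]
    ok <- !is.na(hit)
    ii <- c(ii, which(ok)); jj <- c(jj, unname(hit[ok]))
  }
  adjacency <- Matrix::sparseMatrix(i = ii, j = jj, x = TRUE, dims = c(n, n))
  structure(list(nodes = unname(nodes), spacing = spacing, r_brain = r_brain,
                 connection_radius = connection_radius,
                 adjacency = adjacency),
            class = "solution_grid")
}

#' @export
print.solution_grid <- function(x, ...) {
  cat(sprintf("<solution_grid> %d nodes, spacing %.2f mm, brain radius %.1f mm\n",
              nrow(x$nodes), x$spacing * 1e3, x$r_brain * 1e3))
  invisible(x)
}

# Accumulate the Legendre series for a dipole at scaled eccentricity xb,
# evaluated at surface points with cosine cth against the dipole axis.
# Returns alpha = sum_n T_n xb^(n-1) n P_n(cth) (radial-moment factor) and
# beta = sum_n T_n xb^(n-1) P_n'(cth) (tangential-moment factor).  With
# T_n = 1 this reproduces the free-space dipole potential at the surface,
# which the tests exploit as an independent oracle.
series_alpha_beta <- function(Tn, xb, cth, tol = 1e-10) {
  nE <- length(cth)
  Pprev <- rep(1, nE)          # P_0
  Pcur <- cth                  # P_1
  dPprev <- rep(0, nE)         # P_0'
  dPcur <- rep(1, nE)          # P_1'
  alpha <- Tn[1] * Pcur        # n * P_n at n = 1, xb^0 = 1
  beta <- Tn[1] * dPcur
  pw <- 1
  converged <- xb < 1e-12      # central dipole: only n = 1 survives
  if (!converged) {
    for (n in 2:length(Tn)) {
      Pnext <- ((2 * n - 1) * cth * Pcur - (n - 1) * Pprev) / n
      dPnext <- dPprev + (2 * n - 1) * Pcur
      Pprev <- Pcur; Pcur <- Pnext
      dPprev <- dPcur; dPcur <- dPnext
      pw <- pw * xb
      ta <- Tn[n] * pw * n * Pcur
      tb <- Tn[n] * pw * dPcur
      alpha <- alpha + ta
      beta <- beta + tb
      if (max(max(abs(ta)), max(abs(tb))) <
          tol * max(max(abs(alpha)), max(abs(beta)), 1)) {
        converged <- TRUE
        break
      }
    }
  }
  list(alpha = alpha, beta = beta, converged = converged)
}

#' Analytic three-shell lead field
#'
#' Computes electrode potentials for unit dipoles (SI units: volts per
#' ampere-meter) at every grid node along the three Cartesian orientations,
#' via the Legendre series solution of the concentric-sphere problem, then
#' applies the average reference so every column sums to zero.
#'
#' @param montage a [montage]; its unit positions give the electrode
#'   directions, and electrodes sit on the head model's scalp shell
#' @param grid a [build_solution_grid()] result
#' @param headmodel the [head_model] that generated the grid
#' @return object of class `lead_field`: `matrix` (channels x 3*nodes,
#'   columns grouped per node as x/y/z), plus geometry metadata
#' @export
compute_leadfield <- function(montage, grid, headmodel) {
  stopifnot(inherits(montage, "montage"), inherits(grid, "solution_grid"),
            inherits(headmodel, "head_model"))
  hm <- headmodel
  R <- hm$radii[3]
  if (grid$r_brain > hm$radii[1] + 1e-12) {
    stop("grid extends beyond the brain shell of the (rescaled) head model",
         call. = FALSE)
  }
  Tn <- shell_transfer(hm, hm$n_max)
  U <- montage$positions                       # unit electrode directions
  nE <- nrow(U)
  nN <- nrow(grid$nodes)
  L <- matrix(0, nE, 3 * nN)
  scale0 <- 1 / (4 * pi * hm$conductivities[1] * R^2)
  for (v in seq_len(nN)) {
    p <- grid$nodes[v, ]
    b <- sqrt(sum(p^2))
    zhat <- if (b < 1e-12) c(0, 0, 1) else p / b
    cth <- pmin(1, pmax(-1, as.numeric(U %*% zhat)))
    ab <- series_alpha_beta(Tn, b / R, cth, hm$tol)
    if (!ab$converged) {
      stop(sprintf(
        "lead-field series did not converge for node %d (too close to the brain shell)",
        v), call. = FALSE)
    }
    # Phi(m) = scale0 * [(alpha - beta * c) (m . zhat) + beta (m . u_e)]
    radial_part <- ab$alpha - ab$beta * cth
    for (k in 1:3) {
      L[, 3 * (v - 1) + k] <- scale0 *
        (radial_part * zhat[k] + ab$beta * U[, k])
    }
  }
  L <- sweep(L, 2, colMeans(L))                # average reference
  structure(list(matrix = L, montage = montage, grid = grid,
                 headmodel = hm),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d channels x %d nodes x 3 orientations\n",
              nrow(x$matrix), ncol(x$matrix) / 3))
  invisible(x)
}

#' Depth-weighted minimum-norm inverse operator
#'
#' Builds the weighted minimum-norm (WMN) inverse
#' `J = W^-1 L' (L W^-1 L' + lambda I)^-1 U`, where `W` is diagonal with the
#' per-node lead-field column norm raised to `2*gamma`, replicated over the
#' three orientations.  Depth weighting (`gamma = 1` by default) compensates
#' the minimum-norm bias toward superficial sources; `gamma = 0` recovers the
#' unweighted minimum norm.  When `lambda` is `NULL` it is set from a target
#' signal-to-noise ratio: `lambda = trace(L W^-1 L') / (channels * snr^2)`.
#'
#' @param leadfield a [compute_leadfield()] result
#' @param lambda Tikhonov regularization (>= 0) or `NULL` to derive from `snr`
#' @param gamma depth-weighting exponent
#' @param snr assumed amplitude signal-to-noise ratio (default 3)
#' @return object of class `inverse_operator` with fields `matrix`
#'   ((3*nodes) x channels), `lambda`, `gamma`
#' @export
build_inverse_operator <- function(leadfield, lambda = NULL, gamma = 1,
                                   snr = 3) {
  stopifnot(inherits(leadfield, "lead_field"))
  L <- leadfield$matrix
  nN <- ncol(L) / 3
  node_norm <- sqrt(colSums(matrix(colSums(L^2), nrow = 3)))
  node_norm[node_norm == 0] <- min(node_norm[node_norm > 0])
  w <- rep(node_norm^(2 * gamma), each = 3)
  Lw <- sweep(L, 2, w, "/")                    # L W^-1
  M <- Lw %*% t(L)                             # L W^-1 L'
  if (is.null(lambda)) lambda <- sum(diag(M)) / (nrow(L) * snr^2)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  A <- M + lambda * diag(nrow(L))
  G <- tryCatch(t(Lw) %*% solve(A),
                error = function(e) {
                  stop("singular WMN system; use lambda > 0 for a rank-deficient lead field",
                       call. = FALSE)
                })
  # per-node 3x3 blocks of the resolution matrix G L, for the optional
  # variance-standardized (sLORETA-style) magnitude
  res_blocks <- array(0, dim = c(3, 3, nN))
  for (i in seq_len(nN)) {
    res_blocks[, , i] <- G[3 * (i - 1) + 1:3, , drop = FALSE] %*%
      L[, 3 * (i - 1) + 1:3, drop = FALSE]
  }
  structure(list(matrix = G, lambda = lambda, gamma = gamma,
                 res_blocks = res_blocks, grid = leadfield$grid),
            class = "inverse_operator")
}

#' Apply an inverse operator to an ERP window
#'
#' Estimates distributed source activity for the samples inside
#' `window_ms`, takes the Euclidean norm over the three orientations at
#' each node, and averages over the window.  Values are reported in nominal
#' microampere-per-cubic-millimeter current-density units: the linear WMN
#' estimate of microvolt data, without per-subject conductivity calibration.
#'
#' With `standardized = TRUE` the magnitude is instead the
#' variance-standardized power `sqrt(J_i' R_ii^-1 J_i)` with `R_ii` the
#' node's 3x3 resolution block (the sLORETA standardization), which removes
#' the depth-dependent amplitude bias of the linear estimate; for the
#' unweighted operator (`gamma = 0`) and small `lambda` its peak localizes
#' a noiseless single dipole exactly.
#'
#' @param x an [erp]
#' @param inverse an [build_inverse_operator()] result
#' @param window_ms closed analysis window in ms relative to onset
#'   (default `c(40, 80)`)
#' @param standardized use the variance-standardized magnitude
#' @return numeric vector of node activities (length = number of grid nodes)
#' @export
apply_inverse <- function(x, inverse, window_ms = c(40, 80),
                          standardized = FALSE) {
  stopifnot(inherits(x, "erp"), inherits(inverse, "inverse_operator"))
  idx <- window_to_indices(window_ms, x$srate, x$t0_index, ncol(x$data),
                           "source window")
  J <- inverse$matrix %*% x$data[, idx, drop = FALSE]   # (3N) x T
  nN <- nrow(J) / 3
  if (standardized) {
    mags <- matrix(0, nN, ncol(J))
    for (i in seq_len(nN)) {
      Ji <- J[3 * (i - 1) + 1:3, , drop = FALSE]
      q <- colSums(Ji * solve(inverse$res_blocks[, , i], Ji))
      mags[i, ] <- sqrt(pmax(q, 0))
    }
  } else {
    mags <- sqrt(matrix(colSums(matrix(J^2, nrow = 3)), nrow = nN))
  }
  rowMeans(mags)
}
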