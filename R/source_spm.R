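# Statistical parametric mapping of distributed source estimates:
# node-wise two-sample t-tests, Monte-Carlo calibration of the minimum
# cluster extent on smoothed null fields, and cluster extraction.

# Neighbor lists from the grid's sparse adjacency matrix.
adjacency_neighbors <- function(grid) {
  A <- methods::as(grid$adjacency, "TsparseMatrix")
  split(A@i + 1L, factor(A@j + 1L, levels = seq_len(nrow(grid$nodes))))
}

# Connected components of a node subset under the neighbor lists.
# Returns a list of integer vectors (node ids).
connected_components <- function(nodes, nbrs) {
  if (length(nodes) == 0) return(list())
  in_set <- logical(length(nbrs))
  in_set[nodes] <- TRUE
  seen <- logical(length(nbrs))
  comps <- list()
  for (start in nodes) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, v)
      for (w in nbrs[[v]]) {
        if (in_set[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

#' Node-wise two-sample t-map between groups of source maps
#'
#' Pooled-variance two-sample t at every node; positive t means group A is
#' stronger.  Nodes with zero pooled variance get `t = 0` and are flagged.
#'
#' @param maps_a,maps_b subject x node matrices of source activity
#'   (>= 2 subjects each, same node count)
#' @return list `(t_map, p_map, df, zero_variance)`
#' @export
spm_ttest <- function(maps_a, maps_b) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  stopifnot(nrow(maps_a) >= 2, nrow(maps_b) >= 2,
            ncol(maps_a) == ncol(maps_b))
  na <- nrow(maps_a); nb <- nrow(maps_b)
  df <- na + nb - 2
  ma <- colMeans(maps_a); mb <- colMeans(maps_b)
  va <- apply(maps_a, 2, stats::var); vb <- apply(maps_b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  zero <- se == 0
  tmap <- ifelse(zero, 0, (ma - mb) / se)
  list(t_map = tmap, p_map = 2 * stats::pt(-abs(tmap), df), df = df,
       zero_variance = which(zero))
}

# Sparse Gaussian smoothing operator over the grid with row-normalized
# weights, truncated at twice the FWHM. fwhm <= 0 gives the identity.
build_smoother <- function(grid, fwhm) {
  n <- nrow(grid$nodes)
  if (fwhm <= 0) return(Matrix::Diagonal(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cutoff <- 2 * fwhm
  s <- grid$spacing
  max_off <- floor(cutoff / s)
  offs <- as.matrix(expand.grid(-max_off:max_off, -max_off:max_off,
                                -max_off:max_off))
  d2 <- rowSums(offs^2) * s^2
  keep <- d2 <= cutoff^2 + 1e-12 & d2 > 0
  offs <- offs[keep, , drop = FALSE]
  d2 <- d2[keep]
  ik <- round(grid$nodes / s)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx <- seq_len(n)
  names(idx) <- key(ik)
  ii <- idx; jj <- idx; ww <- rep(1, n)          # self weights
  for (r in seq_len(nrow(offs))) {
    shifted <- sweep(ik, 2, offs[r, ], "+")
    hit <- idx[key(shifted)]
    ok <- !is.na(hit)
    ii <- c(ii, which(ok)); jj <- c(jj, unname(hit[ok]))
    ww <- c(ww, rep(exp(-d2[r] / (2 * sigma^2)), sum(ok)))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
}

# Max same-sign suprathreshold cluster size of a standardized field.
max_cluster_size <- function(z, zthr, nbrs) {
  best <- 0L
  for (sgn in c(1, -1)) {
    nodes <- which(sgn * z > zthr)
    for (comp in connected_components(nodes, nbrs)) {
      if (length(comp) > best) best <- length(comp)
    }
  }
  best
}

#' Monte-Carlo calibration of the minimum significant cluster extent
#'
#' AlphaSim-style bootstrap on the solution grid: each iteration draws an
#' i.i.d. standard-normal field on the nodes, smooths it with a Gaussian
#' kernel of the given FWHM (row-normalized weights over the irregular node
#' set), standardizes each node by its exact post-smoothing SD, thresholds
#' two-sided at the `node_p` quantile, and records the maximum same-sign
#' connected cluster size under the grid adjacency.  The calibrated extent
#' is the smallest `K` with `P(max cluster >= K) <= cluster_alpha`.
#'
#' @param grid a [build_solution_grid()] result (non-empty)
#' @param fwhm smoothing kernel FWHM in meters (default 0.010)
#' @param node_p two-sided node-level threshold (default 0.01)
#' @param cluster_alpha target family-wise error (default 0.05)
#' @param iters Monte-Carlo iterations (>= 100; default 10000)
#' @param seed RNG seed
#' @return list `(min_size, max_sizes, fwe_at_min_size)`
#' @export
calibrate_cluster_threshold <- function(grid, fwhm = 0.010, node_p = 0.01,
                                        cluster_alpha = 0.05, iters = 10000,
                                        seed = 1) {
  stopifnot(inherits(grid, "solution_grid"), iters >= 100,
            nrow(grid$nodes) > 0)
  n <- nrow(grid$nodes)
  W <- build_smoother(grid, fwhm)
  sd_post <- sqrt(Matrix::rowSums(W^2))
  nbrs <- adjacency_neighbors(grid)
  zthr <- stats::qnorm(1 - node_p / 2)
  set.seed(substream_seed(seed, 9001))
  max_sizes <- integer(iters)
  for (it in seq_len(iters)) {
    z <- as.numeric(W %*% stats::rnorm(n)) / sd_post
    max_sizes[it] <- max_cluster_size(z, zthr, nbrs)
  }
  ks <- seq_len(max(max_sizes, 1))
  pk <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  ok <- which(pk <= cluster_alpha)
  min_size <- if (length(ok) == 0) max(max_sizes) + 1L else ks[ok[1]]
  list(min_size = as.integer(min_size), max_sizes = max_sizes,
       fwe_at_min_size = mean(max_sizes >= min_size))
}

#' Extract significant clusters from a t/p map
#'
#' Suprathreshold nodes (`p <= node_p`) are split by the sign of t,
#' connected components under the grid adjacency are formed within each
#' sign, and components smaller than `min_size` are discarded.  The peak
#' node of a cluster maximizes |t|.
#'
#' @param t_map,p_map node-wise statistics (same grid)
#' @param grid the [build_solution_grid()] result
#' @param node_p node-level threshold (default 0.01)
#' @param min_size minimum cluster extent (e.g. from
#'   [calibrate_cluster_threshold()])
#' @return object of class `cluster_result`: `clusters` data.frame
#'   (`size`, `peak_node`, `peak_t`, `sign`), `members` list of node ids,
#'   plus the thresholds used
#' @export
extract_clusters <- function(t_map, p_map, grid, node_p = 0.01,
                             min_size = 20) {
  stopifnot(length(t_map) == nrow(grid$nodes),
            length(p_map) == length(t_map))
  nbrs <- adjacency_neighbors(grid)
  members <- list()
  rows <- list()
  for (sgn in c(1, -1)) {
    nodes <- which(p_map <= node_p & sgn * t_map > 0)
    for (comp in connected_components(nodes, nbrs)) {
      if (length(comp) < min_size) next
      peak <- comp[which.max(abs(t_map[comp]))]
      members[[length(members) + 1]] <- comp
      # |t|-weighted centroid: a far more stable location summary of an
      # extended cluster than its single peak node
      w <- abs(t_map[comp])
      cen <- colSums(grid$nodes[comp, , drop = FALSE] * w) / sum(w) * 1e3
      rows[[length(rows) + 1]] <- data.frame(
        size = length(comp), peak_node = peak, peak_t = t_map[peak],
        sign = sgn, centroid_x_mm = cen[1], centroid_y_mm = cen[2],
        centroid_z_mm = cen[3])
    }
  }
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(size = integer(0), peak_node = integer(0),
               peak_t = numeric(0), sign = integer(0),
               centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
               centroid_z_mm = numeric(0))
  structure(list(clusters = clusters, members = members,
                 node_p = node_p, min_size = min_size,
                 t_map = t_map, p_map = p_map),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), node p <= %g, min size %d\n",
              nrow(x$clusters), x$node_p, x$min_size))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Export a cluster table as TSV
#'
#' One row per cluster with peak-node coordinates in millimeters.
#'
#' @param x a `cluster_result`
#' @param grid the matching grid
#' @param path output file
#' @return `path` invisibly
#' @export
write_cluster_table <- function(x, grid, path) {
  stopifnot(inherits(x, "cluster_result"))
  tab <- x$clusters
  if (nrow(tab) > 0) {
    xyz <- grid$nodes[tab$peak_node, , drop = FALSE] * 1e3
    tab$peak_x_mm <- xyz[, 1]; tab$peak_y_mm <- xyz[, 2]
    tab$peak_z_mm <- xyz[, 3]
    tab$peak_p <- x$p_map[tab$peak_node]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
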