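# Topographic microstate analysis: modified k-means segmentation of grand
# averages, map grouping, minimum-duration smoothing, model-order selection
# by cross-validation / Krzanowski-Lai criteria, and subject-level
# back-fitting with GEV and Duration parameters.

# Center scalp maps to the average reference (column-wise zero mean).
center_maps <- function(maps) sweep(maps, 2, colMeans(maps))

# Spatial correlation between each map (column) and one template.
# Both are average-referenced; templates are unit-norm, so this is the
# Pearson correlation across channels.
spatial_corr <- function(maps, template) {
  nrm <- sqrt(colSums(maps^2))
  nrm[nrm == 0] <- Inf
  as.numeric(crossprod(maps, template)) / nrm
}

# First principal component of a set of maps (columns), sign-oriented to
# correlate positively with the mean assigned map.
dominant_map <- function(maps) {
  if (ncol(maps) == 1) {
    v <- maps[, 1]
  } else {
    v <- eigen(tcrossprod(maps), symmetric = TRUE)$vectors[, 1]
  }
  v <- v - mean(v)
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v <- v / n
  if (sum(v * rowMeans(maps)) < 0) v <- -v
  v
}

# Per-model quality measures. maps: channels x T (average-referenced),
# templates: q x channels unit-norm rows, labels in 1..q.
microstate_criteria <- function(maps, templates, labels) {
  C <- nrow(maps)
  Tn <- ncol(maps)
  q <- nrow(templates)
  proj <- templates[labels, , drop = FALSE]       # T x channels
  dots <- rowSums(t(maps) * proj)                 # tpl' u per sample
  uu <- colSums(maps^2)
  resid <- pmax(uu - dots^2, 0)
  gev_total <- if (sum(uu) > 0) sum(dots^2) / sum(uu) else 1
  sigma2 <- sum(resid) / (Tn * (C - 1))
  cv <- if (q < C - 1) sigma2 * ((C - 1) / (C - 1 - q))^2 else Inf
  list(gev_total = gev_total, sigma2 = sigma2, cv = cv, W = sum(resid))
}

new_microstate_model <- function(maps, templates, labels, srate, t0_index,
                                 window_ms) {
  crit <- microstate_criteria(maps, templates, labels)
  structure(list(q = nrow(templates), templates = templates,
                 labels = labels, maps = maps, srate = srate,
                 t0_index = t0_index, window_ms = window_ms,
                 gev_total = crit$gev_total, sigma2 = crit$sigma2,
                 cv = crit$cv, W = crit$W),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> q = %d, GEV = %.1f%%, CV = %.4g\n",
              x$q, 100 * x$gev_total, x$cv))
  invisible(x)
}

# One modified k-means run from a given template initialization.
modified_kmeans_once <- function(maps, init_idx, max_iter = 200) {
  q <- length(init_idx)
  templates <- t(apply(maps[, init_idx, drop = FALSE], 2, function(v) {
    v <- v - mean(v); v / sqrt(sum(v^2))
  }))
  labels <- rep(1L, ncol(maps))
  for (it in seq_len(max_iter)) {
    r <- vapply(seq_len(q), function(k) spatial_corr(maps, templates[k, ]),
                numeric(ncol(maps)))
    r <- matrix(r, ncol = q)
    new_labels <- max.col(r^2, ties.method = "first")
    for (k in seq_len(q)) {
      idx <- which(new_labels == k)
      if (length(idx) == 0) {
        # re-seed an empty cluster at the worst-fitted sample
        fit <- r[cbind(seq_len(ncol(maps)), new_labels)]^2
        worst <- which.min(fit)
        v <- maps[, worst] - mean(maps[, worst])
        templates[k, ] <- v / sqrt(sum(v^2))
        new_labels[worst] <- k
      } else {
        templates[k, ] <- dominant_map(maps[, idx, drop = FALSE])
      }
    }
    if (all(new_labels == labels) && it > 1) break
    labels <- new_labels
  }
  list(templates = templates, labels = labels)
}

#' Microstate segmentation by modified k-means
#'
#' Concatenates the grand-average ERPs of all groups over the analysis
#' window, average-references every map, and for each candidate number of
#' maps `q` runs a modified k-means: samples are assigned to the template
#' with maximal squared spatial correlation, and each template is recomputed
#' as the first principal component of its assigned maps (so assignment is
#' polarity-insensitive while template signs are oriented by the mean
#' assigned map).  The best of `n_restarts` random restarts by Global
#' Explained Variance (GEV) is kept per `q`.
#'
#' @param grand_avgs list of [erp] grand averages (e.g. one per group)
#' @param window_ms closed segmentation window in ms (default `c(0, 100)`)
#' @param q_range candidate map counts (subset of 1..12)
#' @param n_restarts random restarts per q (default 100)
#' @param seed RNG seed
#' @return named list of `microstate_model`, one per q
#' @export
segment_microstates <- function(grand_avgs, window_ms = c(0, 100),
                                q_range = 1:8, n_restarts = 100, seed = 1) {
  if (inherits(grand_avgs, "erp")) grand_avgs <- list(grand_avgs)
  stopifnot(all(vapply(grand_avgs, inherits, logical(1), "erp")),
            all(q_range >= 1), all(q_range <= 12))
  srate <- grand_avgs[[1]]$srate
  t0 <- grand_avgs[[1]]$t0_index
  maps <- do.call(cbind, lapply(grand_avgs, function(e) {
    idx <- window_to_indices(window_ms, e$srate, e$t0_index, ncol(e$data),
                             "segmentation window")
    e$data[, idx, drop = FALSE]
  }))
  maps <- center_maps(maps)
  n_distinct <- nrow(unique(t(maps)))
  set.seed(substream_seed(seed, 7001))
  models <- lapply(q_range, function(q) {
    if (q > n_distinct) {
      stop(sprintf("q = %d exceeds the %d distinct maps available",
                   q, n_distinct), call. = FALSE)
    }
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- sample.int(ncol(maps), q)
      fit <- modified_kmeans_once(maps, init)
      model <- new_microstate_model(maps, fit$templates, fit$labels,
                                    srate, t0, window_ms)
      if (is.null(best) || model$gev_total > best$gev_total) best <- model
    }
    best
  })
  names(models) <- paste0("q", q_range)
  models
}

#' Merge templates sharing most of their variance
#'
#' While any template pair has squared spatial correlation above
#' `r2_threshold` (default 0.92), the most-correlated pair is replaced by
#' the first principal component of their pooled assigned maps and the
#' labeling updated; `q` decreases accordingly.
#'
#' @param model a `microstate_model`
#' @param r2_threshold squared-correlation merge threshold
#' @return the (possibly reduced) `microstate_model`
#' @export
merge_similar_maps <- function(model, r2_threshold = 0.92) {
  stopifnot(inherits(model, "microstate_model"))
  templates <- model$templates
  labels <- model$labels
  repeat {
    q <- nrow(templates)
    if (q < 2) break
    R2 <- (templates %*% t(templates))^2
    diag(R2) <- 0
    if (max(R2) <= r2_threshold) break
    pair <- which(R2 == max(R2), arr.ind = TRUE)[1, ]
    i <- min(pair); j <- max(pair)
    pooled <- which(labels %in% c(i, j))
    merged <- dominant_map(model$maps[, pooled, drop = FALSE])
    templates[i, ] <- merged
    templates <- templates[-j, , drop = FALSE]
    labels[labels == j] <- i
    labels[labels > j] <- labels[labels > j] - 1L
  }
  new_microstate_model(model$maps, templates, labels, model$srate,
                       model$t0_index, model$window_ms)
}

# Run-length segments of a label vector: data.frame(start, end, label).
label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1, end = ends, label = r$values,
             length = r$lengths)
}

#' Dissolve microstate segments shorter than a minimum duration
#'
#' Segments lasting less than `min_ms` are dissolved sample-by-sample from
#' their edges: each edge sample joins the neighboring segment whose
#' template correlates better with it, until every remaining segment meets
#' the minimum.  Labelings that already satisfy the minimum are unchanged.
#'
#' @param model a `microstate_model`
#' @param min_ms minimum segment duration in ms (default 20)
#' @return the smoothed `microstate_model`
#' @export
enforce_min_duration <- function(model, min_ms = 20) {
  stopifnot(inherits(model, "microstate_model"))
  Tn <- length(model$labels)
  if (Tn * 1000 / model$srate < min_ms) {
    stop("analysis window is shorter than the minimum duration",
         call. = FALSE)
  }
  labels <- model$labels
  dur_ms <- function(len) len * 1000 / model$srate
  corr_with <- function(t, k) {
    u <- model$maps[, t]
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(0)
    (sum(u * model$templates[k, ]) / nu)^2
  }
  repeat {
    runs <- label_runs(labels)
    if (nrow(runs) <= 1) break
    short <- which(dur_ms(runs$length) < min_ms)
    if (length(short) == 0) break
    s <- short[which.min(runs$length[short])]
    left <- if (s > 1) runs$label[s - 1] else NA
    right <- if (s < nrow(runs)) runs$label[s + 1] else NA
    for (t in seq(runs$start[s], runs$end[s])) {
      cand <- stats::na.omit(c(left, right))
      if (length(cand) == 1) {
        labels[t] <- cand
      } else {
        labels[t] <- if (corr_with(t, left) >= corr_with(t, right))
          left else right
      }
    }
  }
  new_microstate_model(model$maps, model$templates, labels, model$srate,
                       model$t0_index, model$window_ms)
}

#' Choose the number of microstate maps
#'
#' Combines the cross-validation (CV) index, which penalizes residual
#' variance by the degrees of freedom, with a modified Krzanowski-Lai (KL)
#' criterion computed from the within-cluster dispersion curve `W(q)`:
#' `DIFF(q) = (q-1)^(2/C) W(q-1) - q^(2/C) W(q)` and
#' `KL(q) = DIFF(q) - DIFF(q+1)`, evaluated only where the dispersion curve
#' is locally convex (`DIFF(q) > 0`, elbow-shaped).  The chosen `q`
#' maximizes KL among candidates whose CV lies within 5 percent of the CV
#' minimum; ties go to the smaller `q`.  If no candidate has a usable KL
#' peak (e.g. structureless data), selection falls back to the CV minimum
#' and says so in the `reason` field.
#'
#' @param models list of `microstate_model` over consecutive q (>= 3 values,
#'   unless a single candidate is supplied)
#' @return list `(q, reason, table)` where `table` collects q, GEV, CV, KL
#' @export
select_microstate_model <- function(models) {
  qs <- unname(vapply(models, function(m) m$q, numeric(1)))
  o <- order(qs)
  models <- models[o]; qs <- qs[o]
  if (length(qs) == 1) {
    return(list(q = qs[1], reason = "single candidate",
                table = data.frame(q = qs, gev = models[[1]]$gev_total,
                                   cv = models[[1]]$cv, kl = NA)))
  }
  if (length(qs) < 3) stop("need at least 3 candidate q values", call. = FALSE)
  C <- nrow(models[[1]]$maps)
  W <- vapply(models, function(m) m$W, numeric(1))
  cv <- vapply(models, function(m) m$cv, numeric(1))
  gev <- vapply(models, function(m) m$gev_total, numeric(1))
  if (all(W <= .Machine$double.eps * 1e3)) {
    # perfect fit everywhere: smallest q already explains the data
    return(list(q = qs[1], reason = "degenerate dispersion (W = 0)",
                table = data.frame(q = qs, gev = gev, cv = cv, kl = NA)))
  }
  diffq <- rep(NA_real_, length(qs))
  for (i in seq_along(qs)) {
    if (i == 1) next
    diffq[i] <- (qs[i] - 1)^(2 / C) * W[i - 1] - qs[i]^(2 / C) * W[i]
  }
  kl <- rep(NA_real_, length(qs))
  for (i in seq_along(qs)) {
    if (i < 2 || i >= length(qs)) next
    if (!is.na(diffq[i]) && diffq[i] > 0) {       # locally convex elbow
      kl[i] <- diffq[i] - diffq[i + 1]
    }
  }
  tab <- data.frame(q = qs, gev = gev, cv = cv, kl = kl)
  cv_ok <- cv <= min(cv) * 1.05
  cand <- which(cv_ok & !is.na(kl))
  if (length(cand) == 0) {
    return(list(q = qs[which.min(cv)],
                reason = "no dominant KL peak; fell back to CV minimum",
                table = tab))
  }
  best <- cand[order(-kl[cand], qs[cand])][1]
  list(q = qs[best], reason = "max KL within 5% of CV minimum", table = tab)
}

#' Back-fit microstate templates into an individual ERP
#'
#' Labels every window sample with the template of maximal squared spatial
#' correlation (winner-take-all, no temporal smoothing) and summarizes each
#' template's presence: `Duration` in ms (labeled samples times the sample
#' period) and `GEV` in percent of the GFP-weighted topographic variance of
#' the window.
#'
#' @param templates template matrix (q x channels) or a `microstate_model`
#' @param subject_erp an [erp]
#' @param window_ms closed fitting window in ms
#' @return data.frame with one row per template: `template`, `gev_pct`,
#'   `duration_ms`
#' @export
fit_templates <- function(templates, subject_erp, window_ms = c(0, 100)) {
  if (inherits(templates, "microstate_model")) templates <- templates$templates
  stopifnot(inherits(subject_erp, "erp"),
            ncol(templates) == nrow(subject_erp$data))
  idx <- window_to_indices(window_ms, subject_erp$srate,
                           subject_erp$t0_index, ncol(subject_erp$data),
                           "fitting window")
  maps <- center_maps(subject_erp$data[, idx, drop = FALSE])
  q <- nrow(templates)
  r <- matrix(vapply(seq_len(q),
                     function(k) spatial_corr(maps, templates[k, ]),
                     numeric(ncol(maps))), ncol = q)
  labels <- max.col(r^2, ties.method = "first")
  uu <- colSums(maps^2)
  dots2 <- (r[cbind(seq_along(labels), labels)])^2 * uu
  denom <- sum(uu)
  data.frame(
    template = seq_len(q),
    gev_pct = vapply(seq_len(q), function(k) {
      if (denom == 0) return(0)
      100 * sum(dots2[labels == k]) / denom
    }, numeric(1)),
    duration_ms = vapply(seq_len(q), function(k) {
      sum(labels == k) * 1000 / subject_erp$srate
    }, numeric(1)))
}

#' Nonparametric group comparison of a microstate fitting parameter
#'
#' Kruskal-Wallis rank test (tie-corrected H, chi-squared df = 1 p-value)
#' of a per-subject parameter between two groups, reported together with
#' Cohen's d from the group means and SDs, as is conventional alongside H.
#'
#' @param values_a,values_b per-subject parameter values (each length >= 2)
#' @return list `(H, df, p, d)`
#' @export
compare_groups_param <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (length(unique(c(values_a, values_b))) == 1) {
    warning("all values identical; H undefined, reported as 0",
            call. = FALSE)
    return(list(H = 0, df = 1, p = 1, d = 0))
  }
  kw <- stats::kruskal.test(list(values_a, values_b))
  sp <- sqrt(((length(values_a) - 1) * stats::var(values_a) +
                (length(values_b) - 1) * stats::var(values_b)) /
               (length(values_a) + length(values_b) - 2))
  d <- if (sp > 0) abs(mean(values_a) - mean(values_b)) / sp else 0
  list(H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
       d = d)
}
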