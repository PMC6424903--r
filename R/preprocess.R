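# Sensor-space cleaning: zero-phase IIR filtering, decimation, threshold
# artifact rejection, baseline correction, average reference, spherical
# spline channel interpolation, and epoch averaging.

# Zero-phase (forward-backward) application of an IIR filter to a vector,
# with odd-reflection padding at both ends to suppress edge transients.
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- c(left, x, right)
  y <- signal::filter(b, a, y)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

apply_filter_epochs <- function(x, b, a, pad) {
  d <- dim(x$data)
  out <- x$data
  for (ep in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out[ep, ch, ] <- filtfilt_padded(b, a, x$data[ep, ch, ], pad)
    }
  }
  x$data <- out
  x
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward Butterworth filtering (order `order` per pass and per
#' section, so the effective magnitude response is squared), applied as a
#' low-pass / high-pass cascade: a single polynomial band-pass spanning
#' 0.25-30 Hz at kHz rates is numerically fragile, while the cascaded
#' sections stay well conditioned.  Odd-reflection padding of at least
#' three time constants of the high-pass corner (capped at the epoch
#' length) suppresses edge transients.
#'
#' @param x an [epochs_set]
#' @param low,high band edges in Hz (defaults 0.25 and 30)
#' @param order Butterworth order per pass (default 4)
#' @return filtered [epochs_set]
#' @export
bandpass_filter <- function(x, low = 0.25, high = 30, order = 4) {
  stopifnot(inherits(x, "epochs_set"))
  nyq <- x$srate / 2
  if (high >= nyq) stop("high edge must be below the Nyquist frequency",
                        call. = FALSE)
  if (low <= 0 || low >= high) stop("need 0 < low < high", call. = FALSE)
  lp <- signal::butter(order, high / nyq, type = "low")
  hp <- signal::butter(order, low / nyq, type = "high")
  pad <- ceiling(3 * x$srate / (2 * pi * low))
  x <- apply_filter_epochs(x, lp$b, lp$a, pad)
  apply_filter_epochs(x, hp$b, hp$a, pad)
}

#' Zero-phase power-line notch filter
#'
#' A biquad notch (constant-Q design, quality factor `q`) applied
#' forward-backward.  With the default `q = 30` a 50 Hz line component is
#' attenuated essentially completely while 45/55 Hz neighbors lose well under
#' half their amplitude.
#'
#' @param x an [epochs_set]
#' @param freq notch frequency in Hz (default 50)
#' @param q quality factor (center frequency / -3 dB bandwidth)
#' @return filtered [epochs_set]
#' @export
notch_filter <- function(x, freq = 50, q = 30) {
  stopifnot(inherits(x, "epochs_set"))
  if (freq >= x$srate / 2) stop("notch frequency must be below Nyquist",
                                call. = FALSE)
  w0 <- 2 * pi * freq / x$srate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  pad <- ceiling(5 * x$srate * q / (pi * freq))
  apply_filter_epochs(x, b, a, pad)
}

#' Downsample by integer decimation
#'
#' Keeps every `srate/target`-th sample, phased so the stimulus-onset sample
#' is retained and `t0_index` is remapped.  The band-pass filter must already
#' have removed content above the new Nyquist frequency.
#'
#' @param x an [epochs_set]
#' @param target new sampling rate in Hz (must divide `srate`)
#' @return decimated [epochs_set]
#' @export
downsample <- function(x, target = 256) {
  stopifnot(inherits(x, "epochs_set"))
  factor <- x$srate / target
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop(sprintf("srate %g is not an integer multiple of target %g",
                 x$srate, target), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  keep <- seq.int(((x$t0_index - 1L) %% factor) + 1L, n_samples(x), by = factor)
  x$data <- x$data[, , keep, drop = FALSE]
  x$t0_index <- as.integer((x$t0_index - 1L) %/% factor + 1L)
  x$srate <- target
  x
}

#' Threshold artifact rejection
#'
#' Drops an epoch iff any channel at any sample exceeds `+threshold` or
#' `-threshold` microvolts (strict comparison: exactly +/-100 is kept).
#'
#' @param x an [epochs_set]
#' @param threshold rejection threshold in microvolts (default 100)
#' @return list with `epochs` (the kept [epochs_set]; zero-epoch sets are
#'   returned with a warning), `rejected` (indices of dropped epochs) and
#'   `report` (counts and percentage)
#' @export
reject_epochs <- function(x, threshold = 100) {
  stopifnot(inherits(x, "epochs_set"), threshold > 0)
  d <- dim(x$data)
  peak <- apply(abs(x$data), 1, max)
  bad <- which(peak > threshold)
  kept <- setdiff(seq_len(d[1]), bad)
  if (length(kept) == 0) {
    warning("all epochs exceeded the rejection threshold", call. = FALSE)
  }
  x$data <- x$data[kept, , , drop = FALSE]
  list(epochs = x, rejected = bad,
       report = list(n_in = d[1], n_rejected = length(bad),
                     pct_rejected = 100 * length(bad) / d[1]))
}

#' Baseline correction
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default -200 ms to stimulus onset).
#'
#' @param x an [epochs_set]
#' @param window_ms closed baseline window in ms (default `c(-200, 0)`)
#' @return corrected [epochs_set]
#' @export
baseline_correct <- function(x, window_ms = c(-200, 0)) {
  stopifnot(inherits(x, "epochs_set"))
  idx <- window_to_indices(window_ms, x$srate, x$t0_index, n_samples(x),
                           "baseline window")
  means <- rowMeans(x$data[, , idx, drop = FALSE], dims = 2)
  x$data <- x$data - as.vector(means)     # recycles over the sample dimension
  x
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels at every sample, for
#' every epoch; afterwards the channel mean is zero everywhere.  Idempotent.
#'
#' @param x an [epochs_set]
#' @return re-referenced [epochs_set]
#' @export
rereference_average <- function(x) {
  stopifnot(inherits(x, "epochs_set"))
  chan_mean <- colMeans(aperm(x$data, c(2, 1, 3)))  # epochs x samples
  d <- dim(x$data)
  x$data <- x$data - aperm(array(chan_mean, dim = c(d[1], d[3], d[2])),
                           c(1, 3, 2))
  x
}

# Perrin et al. spherical-spline kernel g(cos angle) truncated at max_degree.
spline_g <- function(cosang, m = 4, max_degree = 50) {
  p_prev <- rep(1, length(cosang))
  p_cur <- cosang
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:max_degree) {
    p_next <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
    p_prev <- p_cur; p_cur <- p_next
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_cur
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Reconstructs the listed channels of an averaged ERP from the remaining
#' ones with the spherical thin-plate spline on the unit sphere
#' (order `m = 4`, series truncated at degree 50, ridge regularization
#' `reg` on the spline system).  Good channels are returned untouched.
#'
#' @param x an [erp] whose rows follow `montage$labels`
#' @param bad_labels character vector of channels to rebuild (fewer than a
#'   quarter of the montage)
#' @param montage the [montage]
#' @param m spline order
#' @param reg regularization added to the spline system diagonal
#' @param max_degree Legendre series truncation
#' @return the [erp] with interpolated channels
#' @export
interpolate_channels <- function(x, bad_labels, montage, m = 4, reg = 1e-5,
                                 max_degree = 50) {
  stopifnot(inherits(x, "erp"), inherits(montage, "montage"))
  if (length(bad_labels) == 0) return(x)
  if (!all(bad_labels %in% montage$labels)) {
    stop("bad_labels not all present in the montage", call. = FALSE)
  }
  if (nrow(x$data) != length(montage$labels)) {
    stop("ERP channel count does not match the montage", call. = FALSE)
  }
  bad_idx <- match(bad_labels, montage$labels)
  if (length(bad_idx) >= length(montage$labels) / 4) {
    stop("refusing to interpolate a quarter or more of the channels",
         call. = FALSE)
  }
  good_idx <- setdiff(seq_along(montage$labels), bad_idx)
  P <- montage$positions
  G <- spline_g(tcrossprod(P[good_idx, , drop = FALSE]), m, max_degree)
  Gb <- spline_g(P[bad_idx, , drop = FALSE] %*% t(P[good_idx, , drop = FALSE]),
                 m, max_degree)
  ng <- length(good_idx)
  C <- rbind(cbind(G + reg * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  # weights mapping good-channel values directly to bad-channel estimates
  sol <- solve(C, rbind(diag(ng), matrix(0, 1, ng)))
  Wmap <- cbind(Gb, rep(1, length(bad_idx))) %*% sol
  x$data[bad_idx, ] <- Wmap %*% x$data[good_idx, , drop = FALSE]
  x
}

#' Average epochs into an ERP
#'
#' @param x an [epochs_set] with at least one epoch
#' @return an [erp]; `n_epochs` records the contributing count
#' @export
average_epochs <- function(x) {
  stopifnot(inherits(x, "epochs_set"))
  d <- dim(x$data)
  if (d[1] < 1) stop("cannot average an empty epochs set", call. = FALSE)
  avg <- colMeans(x$data)                 # mean over the epoch dimension
  erp(avg, srate = x$srate, t0_index = x$t0_index, n_epochs = d[1],
      channel_labels = x$channel_labels)
}

#' Standard preprocessing chain
#'
#' Applies, in order: band-pass filter, optional notch, optional decimation,
#' threshold rejection, baseline correction and average re-referencing, then
#' averages the surviving epochs into an ERP.  Returns the ERP together with
#' a per-set report of rejection and interpolation percentages.
#'
#' @param x an [epochs_set]
#' @param montage optional [montage] (needed when `bad_labels` is non-empty)
#' @param low,high band-pass edges (Hz)
#' @param notch notch frequency in Hz or `NULL` to skip
#' @param target_srate decimation target or `NULL` to skip
#' @param threshold rejection threshold in microvolts
#' @param baseline_ms baseline window
#' @param bad_labels channels to interpolate in the averaged ERP
#' @return list with `erp`, `report`
#' @export
preprocess_epochs <- function(x, montage = NULL, low = 0.25, high = 30,
                              notch = 50, target_srate = 256,
                              threshold = 100, baseline_ms = c(-200, 0),
                              bad_labels = character(0)) {
  stopifnot(inherits(x, "epochs_set"))
  y <- bandpass_filter(x, low, high)
  if (!is.null(notch)) y <- notch_filter(y, notch)
  if (!is.null(target_srate) && target_srate != y$srate) {
    y <- downsample(y, target_srate)
  }
  rej <- reject_epochs(y, threshold)
  y <- rej$epochs
  y <- baseline_correct(y, baseline_ms)
  y <- rereference_average(y)
  out_erp <- average_epochs(y)
  n_ch <- n_channels(out_erp)
  if (length(bad_labels) > 0) {
    out_erp <- interpolate_channels(out_erp, bad_labels, montage)
  }
  report <- list(subject_id = x$subject_id, group = x$group,
                 condition = x$condition,
                 n_in = rej$report$n_in,
                 n_rejected = rej$report$n_rejected,
                 pct_rejected = rej$report$pct_rejected,
                 n_interpolated = length(bad_labels),
                 pct_interpolated = 100 * length(bad_labels) / n_ch)
  list(erp = out_erp, report = report)
}
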