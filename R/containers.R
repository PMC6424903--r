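#' Epoched EEG for one subject and condition
#'
#' Holds a 3-D array of trials in microvolts together with the sampling rate
#' and the stimulus-onset sample.  Group labels follow the two-group study
#' design (`AP` = absolute pitch, `NAP` = non absolute pitch); conditions are
#' the three closure types (`R` regular, `Tsub` subtle transgression,
#' `Tapp` apparent transgression).
#'
#' @param data numeric array, epochs x channels x samples, in microvolts
#' @param srate sampling rate in Hz (> 0)
#' @param t0_index 1-based sample index of stimulus onset
#' @param subject_id subject identifier
#' @param group group label, `"AP"` or `"NAP"`
#' @param condition condition label, one of `"R"`, `"Tsub"`, `"Tapp"`
#' @param channel_labels optional electrode names (length = dim 2)
#' @return an object of class `epochs_set`
#' @export
epochs_set <- function(data, srate, t0_index, subject_id = "S01",
                       group = c("AP", "NAP"),
                       condition = c("R", "Tsub", "Tapp"),
                       channel_labels = NULL) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  data <- as.array(data)
  if (length(dim(data)) != 3) {
    stop("data must be an epochs x channels x samples array", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("epochs contain non-finite samples", call. = FALSE)
  }
  if (!is.numeric(srate) || srate <= 0) stop("srate must be > 0", call. = FALSE)
  t0_index <- as.integer(t0_index)
  if (t0_index < 1 || t0_index > dim(data)[3]) {
    stop("t0_index outside the recorded samples", call. = FALSE)
  }
  if (!is.null(channel_labels) && length(channel_labels) != dim(data)[2]) {
    stop("channel_labels length does not match channel dimension", call. = FALSE)
  }
  structure(list(data = data, srate = srate, t0_index = t0_index,
                 subject_id = subject_id, group = group,
                 condition = condition,
                 channel_labels = channel_labels),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs_set> %s %s/%s: %d epochs x %d channels x %d samples @ %g Hz (t0 = %d)\n",
    x$subject_id, x$group, x$condition, d[1], d[2], d[3], x$srate, x$t0_index))
  invisible(x)
}

#' Averaged event-related potential
#'
#' @param data numeric matrix, channels x samples, microvolts
#' @param srate sampling rate in Hz
#' @param t0_index 1-based stimulus-onset sample
#' @param n_epochs number of epochs contributing to the average (>= 1)
#' @param channel_labels optional electrode names
#' @return an object of class `erp`
#' @export
erp <- function(data, srate, t0_index, n_epochs = 1L, channel_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("ERP contains non-finite values", call. = FALSE)
  if (n_epochs < 1) stop("n_epochs must be >= 1", call. = FALSE)
  if (!is.numeric(srate) || srate <= 0) stop("srate must be > 0", call. = FALSE)
  t0_index <- as.integer(t0_index)
  if (t0_index < 1 || t0_index > ncol(data)) {
    stop("t0_index outside the ERP samples", call. = FALSE)
  }
  structure(list(data = data, srate = srate, t0_index = t0_index,
                 n_epochs = as.integer(n_epochs),
                 channel_labels = channel_labels),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> %d channels x %d samples @ %g Hz, mean of %d epochs\n",
              nrow(x$data), ncol(x$data), x$srate, x$n_epochs))
  invisible(x)
}

# Shared accessor: number of channels for either container.
n_channels <- function(x) {
  if (inherits(x, "epochs_set")) dim(x$data)[2] else nrow(x$data)
}

n_samples <- function(x) {
  if (inherits(x, "epochs_set")) dim(x$data)[3] else ncol(x$data)
}
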