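#' Convert a latency in milliseconds to a sample index
#'
#' Latencies are expressed in milliseconds relative to stimulus onset
#' (`t0_index`, 1-based).  The mapping rounds toward the nearer sample, so a
#' window stated in ms becomes a closed interval of sample indices.
#'
#' @param ms latency in milliseconds (scalar or vector), 0 = stimulus onset
#' @param srate sampling rate in Hz
#' @param t0_index 1-based sample index of stimulus onset
#' @return integer sample index (same length as `ms`)
#' @export
ms_to_index <- function(ms, srate, t0_index) {
  as.integer(t0_index + round(ms * srate / 1000))
}

#' Convert a sample index to milliseconds relative to stimulus onset
#' @inheritParams ms_to_index
#' @param index 1-based sample index
#' @return latency in ms
#' @export
index_to_ms <- function(index, srate, t0_index) {
  (index - t0_index) * 1000 / srate
}

# Resolve a closed ms window [w1, w2] to sample indices, validating range.
window_to_indices <- function(window_ms, srate, t0_index, n_samples,
                              what = "window") {
  stopifnot(length(window_ms) == 2, window_ms[1] <= window_ms[2])
  idx <- ms_to_index(window_ms, srate, t0_index)
  if (idx[1] < 1 || idx[2] > n_samples) {
    stop(sprintf("%s [%g, %g] ms maps to samples [%d, %d], outside 1..%d",
                 what, window_ms[1], window_ms[2], idx[1], idx[2], n_samples),
         call. = FALSE)
  }
  seq.int(idx[1], idx[2])
}

# Derive a per-stream substream seed from a base seed and a counter, staying
# within the 32-bit signed-integer range R requires of set.seed().
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 65537) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
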