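#' Global Field Power
#'
#' GFP at each sample is the spatial standard deviation of the scalp map
#' across channels, `sqrt(mean((u_i - mean(u))^2))` (population `1/C`
#' normalization), a single always-positive, reference-free measure of
#' response strength.
#'
#' @param x an [erp] with at least 2 channels
#' @return object of class `gfp_curve`: `values` (microvolts, one per
#'   sample), `srate`, `t0_index`
#' @export
gfp <- function(x) {
  stopifnot(inherits(x, "erp"), nrow(x$data) >= 2)
  centered <- sweep(x$data, 2, colMeans(x$data))
  structure(list(values = sqrt(colMeans(centered^2)),
                 srate = x$srate, t0_index = x$t0_index),
            class = "gfp_curve")
}

#' @export
print.gfp_curve <- function(x, ...) {
  cat(sprintf("<gfp_curve> %d samples @ %g Hz, peak %.3f uV\n",
              length(x$values), x$srate, max(x$values)))
  invisible(x)
}

# GFP of a channels x samples matrix (used internally by the microstate
# machinery, which works on raw map matrices).
gfp_of_maps <- function(maps) {
  centered <- sweep(maps, 2, colMeans(maps))
  sqrt(colMeans(centered^2))
}

#' Mean GFP over an analysis window
#'
#' Arithmetic mean of the GFP curve over the closed window (endpoints
#' included), default 40-80 ms.
#'
#' @param x an [erp] or `gfp_curve`
#' @param window_ms closed window in ms relative to onset
#' @return scalar mean GFP in microvolts
#' @export
mean_gfp_window <- function(x, window_ms = c(40, 80)) {
  if (inherits(x, "erp")) x <- gfp(x)
  stopifnot(inherits(x, "gfp_curve"))
  idx <- window_to_indices(window_ms, x$srate, x$t0_index,
                           length(x$values), "GFP window")
  mean(x$values[idx])
}

#' Two-sample comparison of windowed GFP between groups
#'
#' Pooled-variance (Student) two-tailed unpaired t-test on per-subject mean
#' GFP values, with Cohen's d.  The t statistic is oriented second group
#' minus first.
#'
#' @param values_a,values_b numeric vectors of per-subject mean GFP
#'   (each length >= 2)
#' @return list `(t, df, p, d, mean_a, sd_a, mean_b, sd_b)`
#' @export
compare_group_gfp <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  t_from_summary(
    summary_stats(mean(values_a), stats::sd(values_a), length(values_a)),
    summary_stats(mean(values_b), stats::sd(values_b), length(values_b)))
}

#' Collapse condition ERPs into one ERP
#'
#' Epoch-count-weighted mean of the condition ERPs, equivalent to
#' re-averaging all contributing epochs in one pass.
#'
#' @param erps list of [erp] objects sharing srate/t0/channels
#' @return the collapsed [erp]; `n_epochs` is the summed count
#' @export
collapse_conditions <- function(erps) {
  stopifnot(length(erps) >= 1,
            all(vapply(erps, inherits, logical(1), "erp")))
  w <- vapply(erps, function(e) e$n_epochs, numeric(1))
  acc <- Reduce(`+`, Map(function(e, wi) e$data * wi, erps, w)) / sum(w)
  erp(acc, srate = erps[[1]]$srate, t0_index = erps[[1]]$t0_index,
      n_epochs = sum(w), channel_labels = erps[[1]]$channel_labels)
}

#' Export a GFP curve as a single-channel EPH file
#'
#' @param x a `gfp_curve`
#' @param path output file
#' @return `path` invisibly
#' @export
write_gfp_eph <- function(x, path) {
  stopifnot(inherits(x, "gfp_curve"))
  write_eph(erp(matrix(x$values, nrow = 1), srate = x$srate,
                t0_index = x$t0_index), path)
}
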