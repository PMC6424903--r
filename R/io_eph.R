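#' Read and write ERPs in the EPH text format
#'
#' The EPH dialect used by the Cartool ecosystem stores an ERP as plain text:
#' a header line `n_channels n_samples srate`, then one whitespace-separated
#' row per sample with one column per channel.  Values are written with six
#' significant digits, which bounds the roundtrip error at about 1e-6
#' relative.
#'
#' @param path file path
#' @param x an [erp] (for writing)
#' @param t0_index stimulus-onset sample to attach on reading (the format
#'   itself does not carry one); default 1
#' @param n_epochs epoch count to attach on reading; default 1
#' @return `read_eph()` returns an [erp]; `write_eph()` returns `path`
#'   invisibly
#' @export
write_eph <- function(x, path) {
  stopifnot(inherits(x, "erp"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %g", nrow(x$data), ncol(x$data), x$srate), con)
  body <- apply(t(x$data), 1, function(row) {
    paste(formatC(row, format = "g", digits = 6), collapse = " ")
  })
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_eph
#' @export
read_eph <- function(path, t0_index = 1L, n_epochs = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty EPH file: ", path, call. = FALSE)
  hdr <- scan(text = lines[1], quiet = TRUE)
  if (length(hdr) != 3) {
    stop("EPH header must be 'n_channels n_samples srate'", call. = FALSE)
  }
  nc <- as.integer(hdr[1]); ns <- as.integer(hdr[2]); srate <- hdr[3]
  if (length(lines) - 1 != ns) {
    stop(sprintf("EPH body has %d rows but header declares %d samples",
                 length(lines) - 1, ns), call. = FALSE)
  }
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nc * ns) {
    stop(sprintf("EPH body has %d values but header declares %d x %d",
                 length(vals), nc, ns), call. = FALSE)
  }
  # scan() reads row-major (one body row per sample); filling column-major
  # with nrow = nc therefore yields channels x samples directly
  mat <- matrix(vals, nrow = nc)
  erp(mat, srate = srate, t0_index = t0_index, n_epochs = n_epochs)
}
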