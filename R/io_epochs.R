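#' Write / read an epochs container directory
#'
#' The container is a directory holding one JSON metadata document
#' (`meta.json`) plus one raw little-endian float64 array per
#' subject/condition record.  The roundtrip is bitwise lossless for the
#' sample data and preserves sampling rate, onset index, labels and the
#' group/condition metadata.
#'
#' @param x a single [epochs_set] or a list of them
#' @param path container directory (created if missing)
#' @param montage optional [montage]; on reading, a record whose channel
#'   count does not match it is a format error
#' @return `read_epochs_dir()` returns a named list of [epochs_set];
#'   `write_epochs_dir()` returns `path` invisibly
#' @export
write_epochs_dir <- function(x, path) {
  if (inherits(x, "epochs_set")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "epochs_set")))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  records <- vector("list", length(x))
  for (i in seq_along(x)) {
    es <- x[[i]]
    d <- dim(es$data)
    fname <- sprintf("%s_%s_%s.f64", es$subject_id, es$group, es$condition)
    con <- file(file.path(path, fname), "wb")
    writeBin(as.numeric(es$data), con, size = 8, endian = "little")
    close(con)
    records[[i]] <- list(subject_id = es$subject_id, group = es$group,
                         condition = es$condition, file = fname,
                         n_epochs = d[1], n_channels = d[2], n_samples = d[3],
                         srate = es$srate, t0_index = es$t0_index,
                         channel_labels = es$channel_labels)
  }
  jsonlite::write_json(list(format = "erpmicro-epochs-v1", records = records),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_epochs_dir
#' @export
read_epochs_dir <- function(path, montage = NULL) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not an epochs container (missing meta.json): ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  out <- lapply(meta$records, function(rec) {
    n <- rec$n_epochs * rec$n_channels * rec$n_samples
    con <- file(file.path(path, rec$file), "rb")
    vals <- readBin(con, "numeric", n = n, size = 8, endian = "little")
    close(con)
    if (length(vals) != n) {
      stop("truncated data file in container: ", rec$file, call. = FALSE)
    }
    if (!is.null(montage) && rec$n_channels != length(montage$labels)) {
      stop(sprintf(
        "record %s has %d channels but the montage defines %d",
        rec$file, rec$n_channels, length(montage$labels)), call. = FALSE)
    }
    labels <- if (is.null(rec$channel_labels)) NULL else
      unlist(rec$channel_labels)
    epochs_set(array(vals, dim = c(rec$n_epochs, rec$n_channels,
                                   rec$n_samples)),
               srate = rec$srate, t0_index = rec$t0_index,
               subject_id = rec$subject_id, group = rec$group,
               condition = rec$condition, channel_labels = labels)
  })
  names(out) <- vapply(meta$records, function(r)
    paste(r$subject_id, r$condition, sep = "_"), character(1))
  out
}

# ---- minimal EDF (European Data Format) support ---------------------------
# EDF stores a fixed 256-byte ASCII header, 256 ASCII bytes per signal, then
# int16 little-endian data records with per-signal physical/digital scaling.
# Each data record is mapped to one epoch on import.

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(paste0(s, strrep(" ", width)), 1, width)
}

#' Export an epochs set as an EDF file
#'
#' One EDF data record per epoch; samples are quantized to int16 against a
#' symmetric physical range covering the data, so the roundtrip is lossy at
#' the quantization step (about range/65534).
#'
#' @param x an [epochs_set]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_edf <- function(x, path) {
  stopifnot(inherits(x, "epochs_set"))
  d <- dim(x$data)
  ns <- d[2]                                   # signals = channels
  phys_max <- max(1e-6, max(abs(x$data)))
  labels <- x$channel_labels %||% sprintf("EEG%03d", seq_len(ns))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("erpmicro subject", 80),
    edf_pad(paste("erpmicro", x$subject_id, x$group, x$condition), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(d[1], 8), edf_pad(format(d[3] / x$srate, digits = 8), 8),
    edf_pad(ns, 4))
  sig <- paste0(
    paste(vapply(labels, edf_pad, character(1), width = 16), collapse = ""),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad("uV", 8), ns),
    strrep(edf_pad(format(-phys_max, digits = 7), 8), ns),
    strrep(edf_pad(format(phys_max, digits = 7), 8), ns),
    strrep(edf_pad("-32767", 8), ns),
    strrep(edf_pad("32767", 8), ns),
    strrep(edf_pad("", 80), ns),
    strrep(edf_pad(d[3], 8), ns),
    strrep(edf_pad("", 32), ns))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  scale <- 32767 / phys_max
  for (ep in seq_len(d[1])) {
    block <- t(x$data[ep, , , drop = TRUE])     # samples x channels
    writeBin(as.integer(round(block * scale)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Import an EDF file as an epochs set
#'
#' Each EDF data record becomes one epoch; all signals must share a common
#' samples-per-record count.  Physical units are taken as written.
#'
#' @param path EDF file
#' @param t0_index stimulus-onset sample to attach (default 1)
#' @param subject_id,group,condition metadata to attach
#' @return an [epochs_set]
#' @export
read_edf <- function(path, t0_index = 1L, subject_id = "S01",
                     group = "AP", condition = "R") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_rec <- as.integer(fld(hdr, 237, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  seg <- function(block_start, width, i) {
    from <- block_start + (i - 1) * width + 1
    trimws(substr(sig, from, from + width - 1))
  }
  labels <- vapply(seq_len(ns), function(i) seg(0, 16, i), character(1))
  off <- 16 * ns + 80 * ns + 8 * ns
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) seg(off, 8, i),
                                character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) seg(off + 8 * ns, 8, i),
                                character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) seg(off + 16 * ns, 8, i),
                               character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) seg(off + 24 * ns, 8, i),
                               character(1)))
  spr <- as.integer(vapply(seq_len(ns),
                           function(i) seg(off + 32 * ns + 80 * ns, 8, i),
                           character(1)))
  if (length(unique(spr)) != 1) {
    stop("EDF signals with differing sampling rates are not supported",
         call. = FALSE)
  }
  dur <- as.numeric(fld(hdr, 245, 8))
  srate <- spr[1] / dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- array(0, dim = c(n_rec, ns, spr[1]))
  for (rec in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1])          # samples x signals
    for (ch in seq_len(ns)) {
      data[rec, ch, ] <- phys_min[ch] + gain[ch] * (block[, ch] - dig_min[ch])
    }
  }
  epochs_set(data, srate = srate, t0_index = t0_index,
             subject_id = subject_id, group = group, condition = condition,
             channel_labels = labels)
}
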