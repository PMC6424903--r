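#' Electrode montage
#'
#' A montage names the electrodes and places them on a unit sphere; the
#' physical scalp radius (meters) scales the geometry when a head model is
#' attached.  Positions must be unit vectors and labels unique; at least 8
#' electrodes are required for the topographic statistics downstream.
#'
#' @param labels character vector of electrode names
#' @param positions numeric matrix, one row per electrode, columns x/y/z
#'   (x = right, y = front, z = up); rows must have unit norm
#' @param scalp_radius scalp sphere radius in meters (default 0.092)
#' @return an object of class `montage`
#' @export
montage <- function(labels, positions, scalp_radius = 0.092) {
  positions <- as.matrix(positions)
  if (length(labels) != nrow(positions) || ncol(positions) != 3) {
    stop("positions must be a length(labels) x 3 matrix", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("electrode labels must be unique", call. = FALSE)
  if (length(labels) < 8) stop("montage needs at least 8 electrodes", call. = FALSE)
  norms <- sqrt(rowSums(positions^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop("electrode positions must be unit vectors (|norm - 1| <= 1e-9)",
         call. = FALSE)
  }
  if (!is.numeric(scalp_radius) || scalp_radius <= 0) {
    stop("scalp_radius must be positive", call. = FALSE)
  }
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  structure(list(labels = as.character(labels), positions = positions,
                 scalp_radius = scalp_radius),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes, scalp radius %.3f m\n",
              length(x$labels), x$scalp_radius))
  invisible(x)
}

# BioSemi 64-channel label set in standard amplifier order (A1..B32).
biosemi64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
}

# Decompose a 10-10 label into its sagittal row and lateral slot.
# Rows run front to back: Fp, AF, F, FC, C, CP, P, PO, O, I.
parse_1010_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) == 0) stop("unrecognized 10-10 label: ", label, call. = FALSE)
  # temporal labels are the outer slots of the coronal rows
  row <- switch(m[2], T = "C", FT = "FC", TP = "CP", m[2])
  list(row = row, slot = m[3])
}

#' Idealized 64-channel 10-10 montage (BioSemi label set)
#'
#' Synthesizes electrode positions on a unit sphere from the systematic
#' 10-10 arc construction: sagittal rows (Fp, AF, F, FC, C, CP, P, PO, O, I)
#' sit at 18-degree steps along the nasion-inion arc, and lateral slots are
#' obtained by rotating the midline point about the front-back axis in
#' 18-degree steps out to the horizontal 10 percent ring.  These are
#' idealized spherical positions, not digitized cap coordinates.
#'
#' @param scalp_radius scalp radius in meters
#' @return a [montage] with 64 electrodes
#' @export
montage_biosemi64 <- function(scalp_radius = 0.092) {
  labels <- biosemi64_labels()
  # signed midline angle from vertex (degrees, + = front)
  row_beta <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
                CP = -18, P = -36, PO = -54, O = -72, I = -90)
  pos <- t(vapply(labels, function(lb) {
    p <- parse_1010_label(lb)
    beta <- row_beta[[p$row]] * pi / 180
    if (p$slot == "z") {
      gamma <- 0
    } else {
      k <- as.integer(p$slot)
      side <- if (k %% 2 == 1) -1 else 1            # odd = left
      step <- ceiling(k / 2)                        # 1,2->1; 3,4->2; ...
      gamma <- side * min(step * 18, 90) * pi / 180
    }
    c(sin(gamma) * cos(beta), sin(beta), cos(gamma) * cos(beta))
  }, numeric(3)))
  montage(labels, pos, scalp_radius = scalp_radius)
}

#' Read / write a montage as JSON
#'
#' @param path file path
#' @param x a [montage] (for writing)
#' @return `read_montage()` returns a [montage]; `write_montage()` returns
#'   `path` invisibly
#' @export
write_montage <- function(x, path) {
  stopifnot(inherits(x, "montage"))
  obj <- list(labels = x$labels,
              positions = unname(apply(x$positions, 1, as.numeric,
                                       simplify = FALSE)),
              scalp_radius = x$scalp_radius)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- obj$positions
  if (is.list(pos)) pos <- do.call(rbind, pos)
  montage(obj$labels, pos, scalp_radius = obj$scalp_radius)
}
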