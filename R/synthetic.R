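# Two-group, three-condition synthetic ERP study with a planted
# early-latency source-strength difference, used to exercise and validate
# every downstream stage without external recordings.

#' Simulation specification
#'
#' Defines the study conditions emulated by the generator: two groups of
#' pianists (default 11 AP vs 12 NAP), three closure conditions with 90
#' epochs each, 1024 Hz acquisition over a -200..1000 ms epoch, dipolar
#' sources with Gaussian-windowed half-sine time courses, and i.i.d.
#' Gaussian sensor noise.  The planted group effect is a multiplicative
#' boost (`ap_boost`, default 1.5) of the early (peak 60 ms) left
#' temporo-parietal source in the AP group; a later (peak 100 ms) bilateral
#' temporal component is shared by both groups.
#'
#' @param n_ap,n_nap group sizes (defaults 11 and 12)
#' @param epochs_per_condition epochs per condition (default 90)
#' @param srate sampling rate in Hz (default 1024)
#' @param epoch_span_ms epoch extent in ms around stimulus onset
#'   (default `c(-200, 1000)`)
#' @param sources list of source descriptions; each has `location` (meters,
#'   inside the brain shell), `latency_ms`, `width_ms`, `amplitude`
#'   (nanoampere-meters), and `boosted` (logical: scaled by `ap_boost` for
#'   the AP group).  `NULL` uses the default early + bilateral-late layout.
#' @param ap_boost multiplicative factor on boosted sources in the AP group
#' @param noise_sd sensor noise SD in microvolts (default 1.5)
#' @param amplitude_jitter_sd lognormal SD of the per-subject amplitude
#'   jitter (default 0.2)
#' @param artifact_rate fraction of epochs receiving a high-amplitude
#'   frontal artifact (default 0.09, emulating the study's mean trial
#'   rejection rate)
#' @param seed base seed; per-subject substreams are derived from it
#' @return object of class `sim_spec`
#' @export
sim_spec <- function(n_ap = 11, n_nap = 12, epochs_per_condition = 90,
                     srate = 1024, epoch_span_ms = c(-200, 1000),
                     sources = NULL, ap_boost = 1.5, noise_sd = 1.5,
                     amplitude_jitter_sd = 0.2, artifact_rate = 0.09,
                     seed = 1) {
  if (is.null(sources)) sources <- default_sim_sources()
  stopifnot(epochs_per_condition >= 1, srate > 0,
            artifact_rate >= 0, artifact_rate <= 1, ap_boost >= 0,
            noise_sd >= 0)
  for (s in sources) {
    if (s$amplitude < 0) stop("source amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(n_ap = n_ap, n_nap = n_nap,
                 epochs_per_condition = epochs_per_condition,
                 srate = srate, epoch_span_ms = epoch_span_ms,
                 sources = sources, ap_boost = ap_boost,
                 noise_sd = noise_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 artifact_rate = artifact_rate, seed = seed),
            class = "sim_spec")
}

# Default source layout (locations in meters, head frame: x right, y front,
# z up).  Amplitudes were fixed once so that the simulated NAP grand-average
# GFP over 40-80 ms sits near 0.5 microvolts, the scale of real
# early-latency auditory ERPs.
default_sim_sources <- function() {
  list(
    list(name = "early_left_temporoparietal",
         location = c(-0.052, -0.040, 0.020),
         latency_ms = 60, width_ms = 40, amplitude = 23, boosted = TRUE),
    list(name = "late_left_temporal",
         location = c(-0.055, -0.005, 0.010),
         latency_ms = 100, width_ms = 60, amplitude = 27, boosted = FALSE),
    list(name = "late_right_temporal",
         location = c(0.055, -0.005, 0.010),
         latency_ms = 100, width_ms = 60, amplitude = 27, boosted = FALSE))
}

# Gaussian-windowed half-sine time course: a half-sine arch spanning
# [latency - width/2, latency + width/2], tapered by a Gaussian window
# (sigma = width/4) centered on the latency; unit peak amplitude.
source_time_course <- function(t_ms, latency_ms, width_ms) {
  t0 <- latency_ms - width_ms / 2
  inside <- t_ms >= t0 & t_ms <= t0 + width_ms
  h <- ifelse(inside, sin(pi * (t_ms - t0) / width_ms), 0)
  g <- exp(-(t_ms - latency_ms)^2 / (2 * (width_ms / 4)^2))
  h * g
}

# Forward-project one source through the lead field: nearest grid node,
# radial orientation, output in microvolts per (nanoampere-meter).
source_gain_vector <- function(source, leadfield) {
  grid <- leadfield$grid
  loc <- source$location
  if (sqrt(sum(loc^2)) >= grid$r_brain) {
    stop(sprintf("source '%s' lies outside the brain shell",
                 source$name %||% "?"), call. = FALSE)
  }
  d2 <- rowSums(sweep(grid$nodes, 2, loc)^2)
  node <- which.min(d2)
  ori <- grid$nodes[node, ]
  nrm <- sqrt(sum(ori^2))
  ori <- if (nrm < 1e-9) c(0, 0, 1) else ori / nrm
  cols <- leadfield$matrix[, 3 * (node - 1) + 1:3, drop = FALSE]
  # lead field is V / (A m); amplitudes are nA m and data microvolts
  gain <- as.numeric(cols %*% ori) * 1e-9 * 1e6
  list(gain = gain, node = node)
}

#' Simulate one subject (all three conditions)
#'
#' Builds the subject's noise-free sensor signal by forward-projecting every
#' source's time course, applies the subject's lognormal amplitude jitter
#' (drawn from a per-subject substream so any subject is reproducible in
#' isolation; the substream depends only on the within-group index, making
#' groups comparable draw-by-draw), boosts the flagged sources by
#' `ap_boost` for AP subjects, and adds i.i.d. Gaussian sensor noise per
#' epoch.  The three conditions share the signal and differ only in noise.
#'
#' @param spec a [sim_spec]
#' @param group `"AP"` or `"NAP"`
#' @param leadfield a [compute_leadfield()] result (defines montage and grid)
#' @param subject_index within-group subject index (drives the substream)
#' @return named list of three [epochs_set] (R, Tsub, Tapp)
#' @export
simulate_subject <- function(spec, group = c("AP", "NAP"), leadfield,
                             subject_index = 1) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "sim_spec"), inherits(leadfield, "lead_field"))
  montage <- leadfield$montage
  n_ch <- length(montage$labels)
  span <- spec$epoch_span_ms
  n_samp <- round((span[2] - span[1]) * spec$srate / 1000) + 1
  t0_index <- as.integer(1 - round(span[1] * spec$srate / 1000))
  t_ms <- index_to_ms(seq_len(n_samp), spec$srate, t0_index)
  set.seed(substream_seed(spec$seed, subject_index))
  jitter <- exp(stats::rnorm(length(spec$sources), 0,
                             spec$amplitude_jitter_sd))
  signal <- matrix(0, n_ch, n_samp)
  for (i in seq_along(spec$sources)) {
    src <- spec$sources[[i]]
    amp <- src$amplitude * jitter[i]
    if (isTRUE(src$boosted) && group == "AP") amp <- amp * spec$ap_boost
    gv <- source_gain_vector(src, leadfield)
    tc <- source_time_course(t_ms, src$latency_ms, src$width_ms)
    signal <- signal + outer(gv$gain, amp * tc)
  }
  subject_id <- sprintf("%s%02d", group, subject_index)
  out <- lapply(c(R = "R", Tsub = "Tsub", Tapp = "Tapp"), function(cond) {
    dat <- array(0, dim = c(spec$epochs_per_condition, n_ch, n_samp))
    for (ep in seq_len(spec$epochs_per_condition)) {
      noise <- if (spec$noise_sd > 0)
        matrix(stats::rnorm(n_ch * n_samp, 0, spec$noise_sd), n_ch, n_samp)
      else 0
      dat[ep, , ] <- signal + noise
    }
    es <- epochs_set(dat, srate = spec$srate, t0_index = t0_index,
                     subject_id = subject_id, group = group,
                     condition = cond, channel_labels = montage$labels)
    if (spec$artifact_rate > 0) {
      es <- inject_artifacts(es, spec$artifact_rate,
                             seed = substream_seed(spec$seed,
                                                   1000 + subject_index))$epochs
    }
    es
  })
  out
}

#' Simulate the whole two-group study
#'
#' @param spec a [sim_spec]
#' @param leadfield a [compute_leadfield()] result
#' @return nested list: `$AP` / `$NAP`, each a list of per-subject
#'   condition lists from [simulate_subject()]
#' @export
simulate_study <- function(spec, leadfield) {
  stopifnot(inherits(spec, "sim_spec"))
  list(
    AP = lapply(seq_len(spec$n_ap), function(i)
      simulate_subject(spec, "AP", leadfield, i)),
    NAP = lapply(seq_len(spec$n_nap), function(i)
      simulate_subject(spec, "NAP", leadfield, i)))
}

#' Inject high-amplitude frontal artifacts
#'
#' Flags each epoch independently with probability `rate` and adds to the
#' flagged epochs a slow (single-arch) deflection of peak `amplitude`
#' microvolts on the frontal channels (labels starting Fp/AF, or the first
#' four channels when labels are absent), emulating ocular artifacts that
#' the +/-100 microvolt rejection rule must catch.
#'
#' @param x an [epochs_set]
#' @param rate per-epoch artifact probability in `[0, 1]`
#' @param amplitude peak deflection in microvolts (default 150)
#' @param seed RNG seed
#' @return list `(epochs, injected)` where `injected` are the epoch indices
#' @export
inject_artifacts <- function(x, rate, amplitude = 150, seed = 1) {
  stopifnot(inherits(x, "epochs_set"), rate >= 0, rate <= 1)
  if (rate == 0) return(list(epochs = x, injected = integer(0)))
  d <- dim(x$data)
  set.seed(seed)
  flagged <- which(stats::runif(d[1]) < rate)
  if (length(flagged) > 0) {
    labels <- x$channel_labels
    frontal <- if (is.null(labels)) seq_len(min(4, d[2])) else
      grep("^(Fp|AF)", labels)
    if (length(frontal) == 0) frontal <- seq_len(min(4, d[2]))
    arch <- amplitude * sin(pi * (seq_len(d[3]) - 1) / (d[3] - 1))^2
    for (ep in flagged) {
      for (ch in frontal) {
        x$data[ep, ch, ] <- x$data[ep, ch, ] + arch
      }
    }
  }
  list(epochs = x, injected = flagged)
}
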