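# End-to-end pipeline: simulate -> preprocess -> erp -> gfp -> microstates
# -> sources -> behavior -> report, deterministic given the config seeds.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the study defaults:
#' band-pass 0.25-30 Hz, 50 Hz notch, decimation to 256 Hz, +/-100 microvolt
#' rejection, -200..0 ms baseline, 40-80 ms GFP/source window, 0-100 ms
#' microstate window with the 92 percent variance grouping and 20 ms
#' minimum duration, node p <= 0.01 with Monte-Carlo-calibrated cluster
#' extent at alpha 0.05.
#'
#' @param seed master seed for simulation and Monte-Carlo stages
#' @param sim a [sim_spec] (its own seed is overridden by `seed`)
#' @param montage a [montage]; required
#' @param grid_target_count solution-grid node target (default 3005)
#' @param gfp_window_ms,source_window_ms analysis window (ms)
#' @param microstate_window_ms segmentation/fitting window (ms)
#' @param q_range candidate microstate counts
#' @param n_restarts k-means restarts
#' @param merge_r2 squared-correlation grouping threshold
#' @param min_duration_ms minimum microstate duration
#' @param node_p node-level threshold for the source SPM (the 0.005
#'   calibration variant of the study is available by setting this to 0.005)
#' @param cluster_alpha family-wise target of the extent calibration
#' @param calib_iters Monte-Carlo iterations for the extent calibration
#' @param preproc list of preprocessing overrides passed to
#'   [preprocess_epochs()] (`low`, `high`, `notch`, `target_srate`,
#'   `threshold`, `baseline_ms`)
#' @param behavior list of behavioral inputs: `summaries` (named list of
#'   two-group [summary_stats] pairs), `tables` (named list of count
#'   matrices) — defaults are the biographical summaries of the study
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, sim = sim_spec(), montage = NULL,
                            grid_target_count = 3005,
                            gfp_window_ms = c(40, 80),
                            source_window_ms = c(40, 80),
                            microstate_window_ms = c(0, 100),
                            q_range = 1:8, n_restarts = 100,
                            merge_r2 = 0.92, min_duration_ms = 20,
                            node_p = 0.01, cluster_alpha = 0.05,
                            calib_iters = 2000,
                            preproc = list(),
                            behavior = default_behavior_inputs()) {
  if (is.null(montage)) {
    stop("configuration error: a montage is required", call. = FALSE)
  }
  stopifnot(inherits(montage, "montage"), inherits(sim, "sim_spec"))
  sim$seed <- seed
  structure(list(seed = seed, sim = sim, montage = montage,
                 grid_target_count = grid_target_count,
                 gfp_window_ms = gfp_window_ms,
                 source_window_ms = source_window_ms,
                 microstate_window_ms = microstate_window_ms,
                 q_range = q_range, n_restarts = n_restarts,
                 merge_r2 = merge_r2, min_duration_ms = min_duration_ms,
                 node_p = node_p, cluster_alpha = cluster_alpha,
                 calib_iters = calib_iters, preproc = preproc,
                 behavior = behavior),
            class = "pipeline_config")
}

#' Default behavioral inputs (biographical summaries and counts)
#'
#' The published group summaries used for the closed-form behavioral
#' statistics: handedness, age at onset of piano practice, years of piano
#' training and subtle-transgression d-prime as (mean, SD, n) pairs, and
#' gender / secondary-instrument contingency tables.
#'
#' @return list with `summaries` and `tables`
#' @export
default_behavior_inputs <- function() {
  list(
    summaries = list(
      handedness = list(ap = summary_stats(79.43, 23.45, 11),
                        nap = summary_stats(86.75, 10.80, 12)),
      age_onset = list(ap = summary_stats(6.86, 3.67, 11),
                       nap = summary_stats(7.29, 3.32, 12)),
      years_piano = list(ap = summary_stats(17.14, 7.87, 11),
                         nap = summary_stats(15.88, 3.86, 12)),
      dprime_tsub = list(ap = summary_stats(2.28, 1.19, 11),
                         nap = summary_stats(2.22, 1.31, 12))),
    tables = list(
      gender = matrix(c(3, 8, 6, 6), 2,
                      dimnames = list(c("men", "women"), c("AP", "NAP"))),
      secondary_instruments = matrix(c(9, 2, 7, 5), 2,
                                     dimnames = list(c("yes", "no"),
                                                     c("AP", "NAP")))))
}

pipeline_log <- function(logs, stage, msg) {
  c(logs, sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, erp, gfp, microstates, sources and
#' behavior stages and assembles a report.  The run is deterministic given
#' the config seed; any stage failure aborts with the stage name and cause.
#' When `out_dir` is given, `report.json`, `report.txt` and `log.txt` are
#' written there.
#'
#' @param config a [pipeline_config]
#' @param out_dir optional output directory
#' @return the report, a nested list (invisibly when writing to `out_dir`)
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logs <- character(0)
  stage <- "setup"
  report <- list(config = list(seed = config$seed,
                               n_ap = config$sim$n_ap,
                               n_nap = config$sim$n_nap,
                               epochs_per_condition =
                                 config$sim$epochs_per_condition,
                               srate = config$sim$srate,
                               ap_boost = config$sim$ap_boost,
                               noise_sd = config$sim$noise_sd,
                               gfp_window_ms = config$gfp_window_ms,
                               microstate_window_ms =
                                 config$microstate_window_ms,
                               node_p = config$node_p,
                               cluster_alpha = config$cluster_alpha))
  run <- function(stage_name, expr) {
    stage <<- stage_name
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage_name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  hm <- run("setup", head_model())
  grid <- run("setup", build_solution_grid(hm,
                                           target_count =
                                             config$grid_target_count))
  lf <- run("setup", compute_leadfield(config$montage, grid, hm))
  inv <- run("setup", build_inverse_operator(lf))
  logs <- pipeline_log(logs, "setup",
                       sprintf("grid %d nodes, spacing %.2f mm",
                               nrow(grid$nodes), grid$spacing * 1e3))

  # simulate + preprocess + per-subject ERPs (collapsed over conditions)
  stage_preproc <- function(group, n) {
    lapply(seq_len(n), function(i) {
      conds <- simulate_subject(config$sim, group, lf, i)
      pp <- lapply(conds, function(es)
        do.call(preprocess_epochs,
                c(list(x = es, montage = config$montage), config$preproc)))
      erps <- lapply(pp, `[[`, "erp")
      list(erp = collapse_conditions(erps),
           reports = lapply(pp, `[[`, "report"))
    })
  }
  ap <- run("simulate/preprocess", stage_preproc("AP", config$sim$n_ap))
  nap <- run("simulate/preprocess", stage_preproc("NAP", config$sim$n_nap))
  preproc_reports <- c(unlist(lapply(ap, `[[`, "reports"),
                              recursive = FALSE),
                       unlist(lapply(nap, `[[`, "reports"),
                              recursive = FALSE))
  pct <- vapply(preproc_reports, `[[`, numeric(1), "pct_rejected")
  report$preprocessing <- list(
    mean_pct_rejected = mean(pct), sd_pct_rejected = stats::sd(pct),
    per_set = preproc_reports)
  logs <- pipeline_log(logs, "preprocess",
                       sprintf("mean %%rejected = %.2f", mean(pct)))

  # grand averages and GFP statistics
  ga_ap <- run("erp", collapse_conditions(lapply(ap, `[[`, "erp")))
  ga_nap <- run("erp", collapse_conditions(lapply(nap, `[[`, "erp")))
  gfp_ap <- vapply(ap, function(s)
    mean_gfp_window(s$erp, config$gfp_window_ms), numeric(1))
  gfp_nap <- vapply(nap, function(s)
    mean_gfp_window(s$erp, config$gfp_window_ms), numeric(1))
  gfp_test <- run("gfp", compare_group_gfp(gfp_nap, gfp_ap))
  report$gfp <- list(window_ms = config$gfp_window_ms,
                     mean_ap = mean(gfp_ap), sd_ap = stats::sd(gfp_ap),
                     mean_nap = mean(gfp_nap), sd_nap = stats::sd(gfp_nap),
                     t = gfp_test$t, df = gfp_test$df, p = gfp_test$p,
                     d = gfp_test$d)
  logs <- pipeline_log(logs, "gfp",
                       sprintf("AP %.3f vs NAP %.3f uV, t(%d) = %.2f, p = %.4f",
                               mean(gfp_ap), mean(gfp_nap), gfp_test$df,
                               gfp_test$t, gfp_test$p))

  # microstates: segmentation on the two grand averages, then back-fitting
  ms <- run("microstates", {
    models <- segment_microstates(list(ga_ap, ga_nap),
                                  window_ms = config$microstate_window_ms,
                                  q_range = config$q_range,
                                  n_restarts = config$n_restarts,
                                  seed = config$seed)
    models <- lapply(models, merge_similar_maps,
                     r2_threshold = config$merge_r2)
    models <- lapply(models, enforce_min_duration,
                     min_ms = config$min_duration_ms)
    sel <- select_microstate_model(models)
    chosen <- models[[which(vapply(models, `[[`, numeric(1), "q") ==
                              sel$q)[1]]]
    fits_ap <- lapply(ap, function(s)
      fit_templates(chosen, s$erp, config$microstate_window_ms))
    fits_nap <- lapply(nap, function(s)
      fit_templates(chosen, s$erp, config$microstate_window_ms))
    param_tests <- lapply(seq_len(chosen$q), function(k) {
      gev_a <- vapply(fits_ap, function(f) f$gev_pct[k], numeric(1))
      gev_b <- vapply(fits_nap, function(f) f$gev_pct[k], numeric(1))
      dur_a <- vapply(fits_ap, function(f) f$duration_ms[k], numeric(1))
      dur_b <- vapply(fits_nap, function(f) f$duration_ms[k], numeric(1))
      list(template = k,
           gev = c(compare_groups_param(gev_a, gev_b),
                   mean_ap = mean(gev_a), mean_nap = mean(gev_b)),
           duration = c(compare_groups_param(dur_a, dur_b),
                        mean_ap = mean(dur_a), mean_nap = mean(dur_b)))
    })
    list(selection = sel, chosen = chosen, param_tests = param_tests)
  })
  report$microstates <- list(
    q = ms$chosen$q, gev_total = ms$chosen$gev_total,
    selection_reason = ms$selection$reason,
    selection_table = ms$selection$table,
    param_tests = ms$param_tests)
  logs <- pipeline_log(logs, "microstates",
                       sprintf("chosen q = %d (GEV %.1f%%)", ms$chosen$q,
                               100 * ms$chosen$gev_total))

  # source imaging + cluster statistics
  src <- run("sources", {
    maps_ap <- do.call(rbind, lapply(ap, function(s)
      apply_inverse(s$erp, inv, config$source_window_ms)))
    maps_nap <- do.call(rbind, lapply(nap, function(s)
      apply_inverse(s$erp, inv, config$source_window_ms)))
    tt <- spm_ttest(maps_ap, maps_nap)
    calib <- calibrate_cluster_threshold(grid, node_p = config$node_p,
                                         cluster_alpha = config$cluster_alpha,
                                         iters = config$calib_iters,
                                         seed = config$seed)
    cl <- extract_clusters(tt$t_map, tt$p_map, grid,
                           node_p = config$node_p,
                           min_size = calib$min_size)
    list(ttest = tt, calib = calib, clusters = cl)
  })
  cl_tab <- src$clusters$clusters
  report$sources <- list(
    window_ms = config$source_window_ms, node_p = config$node_p,
    min_cluster_size = src$calib$min_size,
    n_clusters = nrow(cl_tab),
    clusters = if (nrow(cl_tab) > 0)
      cbind(cl_tab, peak_x_mm = grid$nodes[cl_tab$peak_node, 1] * 1e3,
            peak_y_mm = grid$nodes[cl_tab$peak_node, 2] * 1e3,
            peak_z_mm = grid$nodes[cl_tab$peak_node, 3] * 1e3)
    else cl_tab,
    peak_t = if (nrow(cl_tab) > 0) cl_tab$peak_t[which.max(abs(cl_tab$peak_t))]
    else NA)
  logs <- pipeline_log(logs, "sources",
                       sprintf("%d cluster(s), min size %d", nrow(cl_tab),
                               src$calib$min_size))

  # behavioral closed-form statistics from the configured inputs
  beh <- run("behavior", {
    ts <- lapply(config$behavior$summaries, function(pair)
      t_from_summary(pair$ap, pair$nap))
    chis <- lapply(config$behavior$tables, chi2_independence)
    list(t_tests = ts, chi2_tests = chis)
  })
  report$behavior <- beh
  logs <- pipeline_log(logs, "behavior",
                       sprintf("%d t-tests, %d chi2 tests",
                               length(beh$t_tests), length(beh$chi2_tests)))

  report$log <- logs
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE,
                         null = "null")
    writeLines(format_report(report), file.path(out_dir, "report.txt"))
    writeLines(logs, file.path(out_dir, "log.txt"))
    return(invisible(report))
  }
  report
}

# Human-readable rendering of the report.
format_report <- function(report) {
  out <- c("== erpmicro pipeline report ==",
           sprintf("seed %d | %d AP vs %d NAP | %d epochs/condition | boost %.2f",
                   report$config$seed, report$config$n_ap,
                   report$config$n_nap, report$config$epochs_per_condition,
                   report$config$ap_boost),
           "",
           sprintf("preprocessing: mean %%rejected %.2f (SD %.2f)",
                   report$preprocessing$mean_pct_rejected,
                   report$preprocessing$sd_pct_rejected),
           sprintf("GFP %d-%d ms: AP %.3f vs NAP %.3f uV | t(%d) = %.2f, p = %.4g, d = %.2f",
                   report$gfp$window_ms[1], report$gfp$window_ms[2],
                   report$gfp$mean_ap, report$gfp$mean_nap, report$gfp$df,
                   report$gfp$t, report$gfp$p, report$gfp$d),
           sprintf("microstates: q = %d, total GEV %.1f%% (%s)",
                   report$microstates$q, 100 * report$microstates$gev_total,
                   report$microstates$selection_reason))
  for (pt in report$microstates$param_tests) {
    out <- c(out, sprintf(
      "  template %d: GEV H = %.2f p = %.4g | Duration H = %.2f p = %.4g",
      pt$template, pt$gev$H, pt$gev$p, pt$duration$H, pt$duration$p))
  }
  out <- c(out, sprintf(
    "sources: %d cluster(s) at node p <= %g, min extent %d",
    report$sources$n_clusters, report$sources$node_p,
    report$sources$min_cluster_size))
  if (report$sources$n_clusters > 0) {
    cl <- report$sources$clusters
    for (i in seq_len(nrow(cl))) {
      out <- c(out, sprintf(
        "  cluster %d: %d nodes, peak t = %.2f at (%.0f, %.0f, %.0f) mm",
        i, cl$size[i], cl$peak_t[i], cl$peak_x_mm[i], cl$peak_y_mm[i],
        cl$peak_z_mm[i]))
    }
  }
  out <- c(out, "behavior:")
  for (nm in names(report$behavior$t_tests)) {
    tt <- report$behavior$t_tests[[nm]]
    out <- c(out, sprintf("  %s: t(%d) = %.2f, p = %.2f, d = %.2f",
                          nm, tt$df, tt$t, tt$p, tt$d))
  }
  for (nm in names(report$behavior$chi2_tests)) {
    ct <- report$behavior$chi2_tests[[nm]]
    out <- c(out, sprintf("  %s: chi2(%d) = %.2f, p = %.2f",
                          nm, ct$df, ct$chi2, ct$p))
  }
  out
}
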