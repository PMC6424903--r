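# Shared fixtures, built lazily and cached for the whole test run.
# Everything is generated in code; no data files are read.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fix_montage <- function() fixture("montage", montage_biosemi64)

fix_headmodel <- function() fixture("headmodel", head_model)

# ~1,000-node grid used by the localization and demo checks
fix_grid <- function() fixture("grid", function()
  build_solution_grid(fix_headmodel(), target_count = 1000))

fix_leadfield <- function() fixture("leadfield", function()
  compute_leadfield(fix_montage(), fix_grid(), fix_headmodel()))

fix_inverse <- function() fixture("inverse", function()
  build_inverse_operator(fix_leadfield()))

# Reduced demo study: 6 vs 6 subjects, 30 epochs/condition at 256 Hz,
# analyzed through the full pipeline on the ~1,000-node grid.
fix_demo_report <- function() fixture("demo_report", function() {
  cfg <- pipeline_config(
    seed = 5,
    sim = sim_spec(n_ap = 6, n_nap = 6, epochs_per_condition = 30,
                   srate = 256),
    montage = fix_montage(), grid_target_count = 1000,
    calib_iters = 1000,
    preproc = list(notch = NULL, target_srate = NULL))
  run_pipeline(cfg)
})

# The grid node nearest the planted early source.
planted_node <- function(grid) {
  which.min(rowSums(sweep(grid$nodes, 2, c(-0.052, -0.040, 0.020))^2))
}

# Agreement with a value printed at 2 decimals: the recomputed statistic
# must round-trip into the printed value's last-digit band.  (Printed
# summaries are themselves rounded, so exact round() equality is brittle.)
expect_printed <- function(value, printed, digits = 2) {
  expect_lt(abs(value - printed), 1.05 * 10^(-digits))
}

# Construct a sample with exactly the given mean and SD (n = 3).
sample_with_stats <- function(m, s) c(m - s, m, m + s)

# Build a microstate model directly from maps/templates/labels (bypassing
# segmentation) for tests of the smoothing and merging operators.
new_model_for_test <- function(maps, templates, labels, srate) {
  erpmicro:::new_microstate_model(maps, templates, labels, srate, 1L,
                                  c(0, (ncol(maps) - 1) * 1000 / srate))
}

# Concatenate two epochs arrays along the epoch dimension.
abind_epochs <- function(a, b) {
  stopifnot(all(dim(a)[-1] == dim(b)[-1]))
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
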