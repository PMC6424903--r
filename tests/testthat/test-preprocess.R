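# Filtering, decimation, rejection, baseline, reference, spline
# interpolation and averaging.

sine_epochs <- function(freq, srate = 1024, secs = 4, amp = 1) {
  t <- seq(0, secs, by = 1 / srate)
  epochs_set(array(rep(amp * sin(2 * pi * freq * t), each = 2),
                   c(1, 2, length(t))),
             srate = srate, t0_index = 1)
}

# steady-state amplitude, ignoring the outer 20% at each edge
steady_amp <- function(es) {
  n <- dim(es$data)[3]
  core <- seq.int(ceiling(n * 0.2), floor(n * 0.8))
  max(abs(es$data[1, 1, core]))
}

test_that("band-pass keeps the passband and removes drift with zero phase", {
  expect_equal(steady_amp(bandpass_filter(sine_epochs(10))), 1,
               tolerance = 0.02)
  drift <- sine_epochs(0.01, secs = 8)
  expect_lt(steady_amp(bandpass_filter(drift)), 0.1)   # > 90% attenuation
  # symmetric impulse in, symmetric response out (zero phase)
  n <- 1025
  imp <- epochs_set(array(rep(c(numeric(512), 1, numeric(512)), each = 2),
                          c(1, 2, n)), 1024, 1)
  out <- bandpass_filter(imp)$data[1, 1, ]
  mid <- 513
  expect_lt(max(abs(out[(mid + 1):(mid + 200)] - out[(mid - 1):(mid - 200)])),
            1e-3 * max(abs(out)))
  expect_error(bandpass_filter(sine_epochs(10, srate = 50), high = 30),
               "Nyquist")
})

test_that("notch removes the line frequency but spares its neighbors", {
  expect_lt(steady_amp(notch_filter(sine_epochs(50))), 0.05)
  expect_gte(steady_amp(notch_filter(sine_epochs(10))), 0.95)
  expect_gt(steady_amp(notch_filter(sine_epochs(45))), 0.5)
  expect_gt(steady_amp(notch_filter(sine_epochs(55))), 0.5)
  dc <- epochs_set(array(5, c(1, 2, 1000)), 1024, 1)
  expect_equal(notch_filter(dc)$data, dc$data, tolerance = 1e-3)
})

test_that("decimation keeps counts, constants, tones and the onset sample", {
  es <- epochs_set(array(1, c(1, 2, 1024)), 1024, 257)
  out <- downsample(es, 256)
  expect_equal(dim(out$data)[3], 256)
  expect_equal(out$srate, 256)
  expect_true(all(out$data == 1))
  # onset remains on a kept sample at the remapped index
  expect_equal(index_to_ms(out$t0_index, out$srate, out$t0_index), 0)
  expect_equal((es$t0_index - 1) %% 4, (0))
  # a 10 Hz tone survives decimation with its amplitude
  tone <- sine_epochs(10)
  dec <- downsample(tone, 256)
  expect_equal(steady_amp(dec), 1, tolerance = 0.02)
  expect_error(downsample(es, 300), "integer")
})

test_that("threshold rejection is strict at +/-100 microvolts", {
  base <- array(0, c(3, 2, 10))
  base[1, 1, 5] <- 101
  base[2, 2, 3] <- 100          # exactly at threshold: kept
  base[3, 1, 9] <- -100.5
  es <- epochs_set(base, 256, 1)
  res <- reject_epochs(es)
  expect_equal(res$rejected, c(1, 3))
  expect_equal(dim(res$epochs$data)[1], 1)
  expect_equal(res$report$pct_rejected, 200 / 3)
  expect_warning(reject_epochs(epochs_set(array(200, c(2, 2, 4)), 256, 1)),
                 "all epochs")
})

test_that("baseline correction zeroes the baseline mean exactly", {
  es <- epochs_set(array(5, c(2, 3, 100)), 256, 52)
  out <- baseline_correct(es)
  expect_true(all(out$data == 0))
  # already zero-mean baseline is untouched; window outside errors
  set.seed(9)
  d <- array(stats::rnorm(2 * 3 * 100), c(2, 3, 100))
  es2 <- epochs_set(d, 256, 52)
  bc <- baseline_correct(es2)
  idx <- ms_to_index(-200, 256, 52):52
  for (ep in 1:2) for (ch in 1:3) {
    expect_equal(mean(bc$data[ep, ch, idx]), 0, tolerance = 1e-12)
  }
  expect_error(baseline_correct(es, c(-400, 0)), "outside")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(10)
  es <- epochs_set(array(stats::rnorm(2 * 5 * 20), c(2, 5, 20)), 256, 1)
  out <- rereference_average(es)
  expect_equal(max(abs(apply(out$data, c(1, 3), mean))), 0,
               tolerance = 1e-12)
  expect_equal(rereference_average(out)$data, out$data, tolerance = 1e-12)
  # GFP is reference-free: unchanged by re-referencing
  e1 <- average_epochs(es)
  e2 <- average_epochs(out)
  expect_equal(gfp(e1)$values, gfp(e2)$values, tolerance = 1e-12)
})

test_that("spherical spline recovers harmonic fields and smooth ERP channels", {
  mon <- fix_montage()
  # first-order spherical harmonic u = c * z
  u <- 3 * mon$positions[, 3]
  x <- erp(matrix(u, ncol = 1), 256, 1)
  out <- interpolate_channels(x, "C3", mon)
  i <- match("C3", mon$labels)
  expect_equal(out$data[i, 1], unname(u[i]), tolerance = 0.01)
  # untouched good channels, identity for empty bads
  expect_equal(out$data[-i, ], x$data[-i, ], tolerance = 1e-12)
  expect_identical(interpolate_channels(x, character(0), mon), x)
  # a smooth synthetic ERP channel is recovered with r > 0.95
  lf <- fix_leadfield()
  spec <- sim_spec(n_ap = 1, n_nap = 1, epochs_per_condition = 4,
                   srate = 256, noise_sd = 0, artifact_rate = 0, seed = 3)
  es <- simulate_subject(spec, "AP", lf, 1)$R
  true_erp <- average_epochs(es)
  interp <- interpolate_channels(true_erp, "CP5", mon)
  j <- match("CP5", mon$labels)
  expect_gt(stats::cor(interp$data[j, ], true_erp$data[j, ]), 0.95)
  expect_error(interpolate_channels(x, mon$labels[1:20], mon), "quarter")
  expect_error(interpolate_channels(x, "nope", mon), "montage")
})

test_that("epoch averaging is the pointwise mean with the count recorded", {
  d <- array(0, c(4, 2, 5))
  for (ep in 1:4) d[ep, , ] <- ep
  es <- epochs_set(d, 256, 1)
  avg <- average_epochs(es)
  expect_true(all(avg$data == 2.5))
  expect_equal(avg$n_epochs, 4)
  # variance of the mean of n i.i.d. noise epochs shrinks like sigma^2/n
  set.seed(20)
  n <- 100
  noise <- epochs_set(array(stats::rnorm(n * 2 * 200, sd = 2),
                            c(n, 2, 200)), 256, 1)
  v <- stats::var(as.numeric(average_epochs(noise)$data))
  expect_lt(abs(v - 4 / n) / (4 / n), 0.3)
})
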