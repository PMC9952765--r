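test_that("displacement generator honours its ground-truth contract", {
  # null motion
  p0 <- motion_profile("resting_tremor", displacement_amplitude = 0)
  g0 <- generate_displacement(p0, fs = 500, duration = 20)
  expect_true(all(g0$displacement == 0))
  expect_equal(g0$ground_truth$true_count, 0L)

  # fixed 5 Hz, 10 s active -> 50 cycles; verify by zero-crossing count
  p5 <- motion_profile("resting_tremor", frequency_spec = 5)
  g5 <- generate_displacement(p5, fs = 1000, duration = 20)
  expect_equal(g5$ground_truth$true_count, 50L)
  d <- g5$displacement[5001:15000]
  up_crossings <- sum(d[-1] > 0 & d[-length(d)] <= 0)
  expect_equal(up_crossings, 50L)
  expect_equal(g5$ground_truth$true_mean_frequency, 5, tolerance = 1e-9)
  expect_equal(g5$ground_truth$true_duration, 10)

  # zero outside the active interval
  expect_true(all(g5$displacement[1:5000] == 0))
  expect_true(all(g5$displacement[15001:20000] == 0))
})

test_that("tremor per-cycle frequencies stay inside the configured range", {
  for (s in 1:5) {
    p <- motion_profile("resting_tremor", frequency_spec = c(3, 6))
    g <- generate_displacement(p, fs = 1000, duration = 20, seed = s)
    f <- g$ground_truth$cycle_frequencies
    expect_true(all(f >= 3 & f <= 6))
    expect_equal(length(f), g$ground_truth$true_count)
  }
})

test_that("invalid motion configurations are rejected", {
  p <- motion_profile("resting_tremor", frequency_spec = 600)
  expect_error(generate_displacement(p, fs = 1000, duration = 20),
               "Nyquist")
  p2 <- motion_profile("resting_tremor", start = 15, active_duration = 10)
  expect_error(generate_displacement(p2, fs = 1000, duration = 20),
               "past the end")
})

test_that("static noiseless channel has time-constant basic signals", {
  prof <- motion_profile("resting_tremor", displacement_amplitude = 0,
                         start = 0, active_duration = 1)
  scn <- scene_config(noise_sd = 0, n_subcarriers = 30L, duration = 2)
  for (mode in c("geometric", "direct")) {
    rec <- synthesize_csi(scn, prof, mode = mode)
    amp <- extract_amplitude(rec)$values
    expect_lt(max(apply(amp, 2, function(x) diff(range(x)))), 1e-12)
    ph <- extract_phase(rec, sanitize = FALSE)$values
    expect_lt(max(apply(ph, 2, function(x) diff(range(x)))), 1e-12)
  }
})

test_that("sub-wavelength sinusoidal motion puts the FFT peak at its frequency", {
  prof <- motion_profile("resting_tremor", frequency_spec = 5,
                         displacement_amplitude = 1e-3,
                         start = 0, active_duration = 10)
  scn <- scene_config(noise_sd = 0, n_subcarriers = 30L, duration = 10)
  rec <- synthesize_csi(scn, prof, mode = "geometric")
  amp <- extract_amplitude(rec)$values[, 1]
  spec <- compute_spectrum(amp - mean(amp), fs = 1000)
  f_peak <- spec$frequency[which.max(spec$magnitude)]
  expect_equal(f_peak, 5, tolerance = 0.11)  # one bin at 0.1 Hz resolution
})

test_that("tangential motion barely modulates the channel", {
  scn <- scene_config(noise_sd = 0, n_subcarriers = 30L, duration = 10)
  grad <- c(scn$motion_pos - scn$tx_pos) /
    sqrt(sum((scn$motion_pos - scn$tx_pos)^2)) +
    c(scn$motion_pos - scn$rx_pos) /
    sqrt(sum((scn$motion_pos - scn$rx_pos)^2))
  perp_dir <- grad / sqrt(sum(grad^2))
  tang_dir <- c(-perp_dir[2], perp_dir[1])
  mk <- function(dir) {
    prof <- motion_profile("resting_tremor", frequency_spec = 5,
                           displacement_amplitude = 0.02,
                           start = 0, active_duration = 10,
                           direction = dir)
    rec <- synthesize_csi(scn, prof, mode = "geometric")
    mean(apply(extract_amplitude(rec)$values, 2, var))
  }
  expect_lt(mk(tang_dir), 0.01 * mk(perp_dir))
})

test_that("a fixed seed reproduces the recording bit for bit", {
  prof <- motion_profile("resting_tremor", start = 0.5,
                         active_duration = 4)
  scn <- scene_config(noise_sd = 0.05, n_subcarriers = 30L, duration = 5,
                      seed = 77)
  r1 <- synthesize_csi(scn, prof)
  r2 <- synthesize_csi(scn, prof)
  expect_identical(r1$samples, r2$samples)
})

test_that("modulation depth grows with reflection gain", {
  prof <- motion_profile("resting_tremor", frequency_spec = 5,
                         displacement_amplitude = 1e-3,
                         start = 0, active_duration = 5)
  depths <- vapply(c(0.5, 1, 2), function(g) {
    scn <- scene_config(noise_sd = 0, n_subcarriers = 30L, duration = 5,
                        reflection_gain = g)
    amp <- extract_amplitude(synthesize_csi(scn, prof))$values[, 1]
    diff(range(amp))
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("packet loss injection follows its replacement model", {
  rec <- random_recording(200L, 30L, seed = 21)
  expect_identical(inject_packet_loss(rec, 0)$samples, rec$samples)

  all_lost <- inject_packet_loss(rec, 1)
  expect_true(all(all_lost$samples ==
                  matrix(rec$samples[1, ], 200, 30, byrow = TRUE)))

  # repeated-row count within 3 binomial SDs of rate * (T - 1)
  big <- random_recording(20000L, 30L, seed = 22)
  lossy <- inject_packet_loss(big, 0.1, seed = 23)
  n_rep <- sum(rowSums(lossy$samples[-1, ] != lossy$samples[-20000, ]) == 0)
  expected <- 0.1 * 19999
  sd3 <- 3 * sqrt(19999 * 0.1 * 0.9)
  expect_lt(abs(n_rep - expected), sd3)
})

test_that("slow-response envelope attenuates the motion onset", {
  prof <- motion_profile("resting_tremor", frequency_spec = 5)
  scn <- scene_config(noise_sd = 0, n_subcarriers = 30L, seed = 4)
  rec <- synthesize_csi(scn, prof, mode = "geometric")

  expect_identical(inject_slow_response(rec, 0, 0)$samples, rec$samples)

  slow <- inject_slow_response(rec, 0.5, 0.5)
  motion0 <- sweep(rec$samples, 2, rec$meta$static_gain, `-`)
  motion1 <- sweep(slow$samples, 2, slow$meta$static_gain, `-`)
  i0 <- rec$meta$active_index[1]
  # first active sample attenuated below 10% of the unramped value
  expect_lt(Mod(motion1[i0 + 1, 1]), 0.1 * Mod(motion0[i0 + 1, 1]))
  # a trapezoidal envelope never amplifies
  expect_true(all(Mod(motion1) <= Mod(motion0) + 1e-9))
})

test_that("reference trace mimics a 200 Hz accelerometer", {
  prof5 <- motion_profile("resting_tremor", frequency_spec = 5)
  tr <- generate_reference_trace(prof5, duration = 20, seed = 6)
  expect_equal(length(tr$values), 200 * 20)
  expect_equal(tr$fs, 200)

  q <- quantify_reference(tr, f_max = 6)
  expect_equal(q$count, tr$ground_truth$true_count)

  null_prof <- motion_profile("resting_tremor", displacement_amplitude = 0)
  tr0 <- generate_reference_trace(null_prof, duration = 20, noise_sd = 0.05)
  # sensor noise only: zero-mean, at the configured scale
  expect_lt(abs(mean(tr0$values)), 0.01)
  expect_lt(max(abs(tr0$values)), 0.05 * 6)
})
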