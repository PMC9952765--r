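test_that("recording constructor enforces its invariants", {
  expect_error(csi_recording(matrix(1 + 0i, 5, 29), fs = 1000),
               "multiple of 30")
  expect_error(csi_recording(matrix(complex(real = NA), 2, 30), fs = 1000),
               "NA")
  expect_error(csi_recording(matrix(1 + 0i, 2, 30), fs = -1), "fs")
  rec <- csi_recording(matrix(1 + 2i, 4, 60), fs = 1000)
  expect_s3_class(rec, "csi_recording")
  expect_equal(nrow(rec$streams), 2L)
  expect_equal(stream_columns(rec, 2), 31:60)
})

test_that("amplitude is the elementwise modulus", {
  rec1 <- csi_recording(matrix(1 + 0i, 1, 30), fs = 1000)
  expect_equal(extract_amplitude(rec1)$values,
               matrix(1, 1, 30))
  rec2 <- csi_recording(matrix(3 + 4i, 1, 30), fs = 1000)
  expect_equal(extract_amplitude(rec2)$values, matrix(5, 1, 30))

  rec <- random_recording(10L, 30L, seed = 42)
  amp <- extract_amplitude(rec)$values
  brute <- sqrt(Re(rec$samples)^2 + Im(rec$samples)^2)
  expect_equal(amp, brute, tolerance = 1e-12)
  expect_true(all(amp >= 0))
})

test_that("amplitude is invariant under a global unit-modulus rotation", {
  rec <- random_recording(20L, 30L, seed = 7)
  rot <- rec
  rot$samples <- rec$samples * exp(1i * 1.234)
  expect_equal(extract_amplitude(rot)$values,
               extract_amplitude(rec)$values, tolerance = 1e-12)
})

test_that("raw phase follows the argument with the (-pi, pi] convention", {
  rec <- csi_recording(matrix(5 + 0i, 1, 30), fs = 1000)
  expect_equal(extract_phase(rec, sanitize = FALSE)$values,
               matrix(0, 1, 30))
  rec2 <- csi_recording(matrix(0 + 2i, 1, 30), fs = 1000)
  expect_equal(extract_phase(rec2, sanitize = FALSE)$values,
               matrix(pi / 2, 1, 30))
  # the wrap boundary maps to +pi, never -pi
  rec3 <- csi_recording(matrix(-1 + 0i, 1, 30), fs = 1000)
  expect_equal(extract_phase(rec3, sanitize = FALSE)$values,
               matrix(pi, 1, 30))
})

test_that("sanitization removes an exactly linear phase ramp", {
  slope <- 0.13; offset <- 0.71
  ph <- outer(rep(1, 8), offset + slope * (1:30))
  samples <- exp(1i * ph)
  rec <- csi_recording(samples, fs = 1000)
  out <- extract_phase(rec, sanitize = TRUE)$values
  expect_lt(max(abs(out)), 1e-9)
})

test_that("phase difference obeys its algebraic contracts", {
  rec <- random_recording(15L, 60L, seed = 3)
  expect_warning(d_same <- extract_phase_difference(rec, 1, 1),
                 "identically zero")
  expect_equal(d_same$values, matrix(0, 15, 30))

  # stream 2 = stream 1 rotated by e^{i pi/4} -> constant difference -pi/4
  rot <- rec
  rot$samples[, 31:60] <- rec$samples[, 1:30] * exp(1i * pi / 4)
  d <- extract_phase_difference(rot, 1, 2)$values
  expect_equal(d, matrix(-pi / 4, 15, 30), tolerance = 1e-12)

  # antiphase streams -> pi under the (-pi, pi] convention
  anti <- rec
  anti$samples[, 31:60] <- -rec$samples[, 1:30]
  da <- extract_phase_difference(anti, 1, 2)$values
  expect_true(all(abs(da) == pi))

  # antisymmetry: diff(a, b) = wrap(-diff(b, a))
  d12 <- extract_phase_difference(rec, 1, 2)$values
  d21 <- extract_phase_difference(rec, 2, 1)$values
  w <- -d21
  w <- (w + pi) %% (2 * pi) - pi; w[w == -pi] <- pi
  expect_equal(d12, w, tolerance = 1e-12)
})

test_that("CSI ratio matches brute-force division and its invariances", {
  rec <- random_recording(15L, 60L, seed = 5)
  r <- compute_csi_ratio(rec, 1, 2)$values
  brute <- Mod(rec$samples[, 1:30]) / Mod(rec$samples[, 31:60])
  expect_equal(r, brute, tolerance = 1e-12)

  expect_equal(compute_csi_ratio(rec, 1, 1)$values, matrix(1, 15, 30),
               tolerance = 1e-12)

  six_three <- csi_recording(
    cbind(matrix(6 + 0i, 4, 30), matrix(3 + 0i, 4, 30)), fs = 1000)
  expect_equal(compute_csi_ratio(six_three, 1, 2)$values,
               matrix(2, 4, 30))

  # common positive gain cancels
  g <- rec; g$samples <- rec$samples * 3.7
  expect_equal(compute_csi_ratio(g, 1, 2)$values, r, tolerance = 1e-12)
})

test_that("near-zero ratio denominators are imputed from neighbors", {
  rec <- random_recording(10L, 60L, seed = 9)
  rec$samples[4L, 31L] <- 0 + 0i
  expect_message(r <- compute_csi_ratio(rec, 1, 2),
                 "1 near-zero denominator")
  # imputed from nearest valid time step of the same subcarrier
  expect_equal(r$values[4L, 1L], r$values[3L, 1L])
  expect_true(all(is.finite(r$values)))
})

test_that("CSV and binary round trips preserve the recording", {
  rec <- random_recording(8L, 30L, seed = 12)
  rec$meta <- list(note = "fixture", seed = 12)
  tmp <- file.path(tempdir(), "rt")
  write_csi_csv(rec, tmp)
  back <- read_csi_csv(tmp)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$meta$note, "fixture")

  write_csi_bin(rec, tmp)
  bin <- read_csi_bin(tmp)
  expect_identical(bin$samples, rec$samples)
})
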