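#' Scene configuration for the synthetic CSI simulator
#'
#' Describes the room, the WiFi link and the channel parameters of a
#' simulated capture.  Defaults mirror the reference measurement setup:
#' a 4.2 m x 7.9 m room, a single transmitter-receiver link at 5 GHz /
#' 20 MHz bandwidth, 1000 Hz CSI sampling, 20 s recordings, and motion
#' 1 m from the midpoint of the line of sight.
#'
#' @param room width/length in metres, `c(w, l)`.
#' @param tx_pos,rx_pos transmitter / receiver 2-D coordinates (m).
#' @param motion_pos location of the moving target (m).
#' @param carrier_freq carrier frequency (Hz).
#' @param subcarrier_spacing spacing between adjacent subcarrier centre
#'   frequencies (Hz); defaults to 20 MHz / 30.
#' @param n_subcarriers total subcarrier count (multiple of 30; 180 = the
#'   full six-stream capture).
#' @param static_gain complex static multipath background per subcarrier
#'   (scalar recycled, vector of length `n_subcarriers`, or `NULL` for the
#'   default gain 20 with a mild per-subcarrier phase ramp).
#' @param reflection_gain amplitude of the reflected (motion) path.
#' @param noise_sd standard deviation of the additive complex Gaussian
#'   noise, per real/imaginary component.
#' @param fs CSI sampling rate (Hz).
#' @param duration recording length (s).
#' @param seed integer seed making the simulated capture reproducible.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(room = c(4.2, 7.9),
                         tx_pos = c(1.1, 3.95), rx_pos = c(3.1, 3.95),
                         motion_pos = c(2.1, 2.95),
                         carrier_freq = 5e9,
                         subcarrier_spacing = 20e6 / 30,
                         n_subcarriers = 180L,
                         static_gain = NULL,
                         reflection_gain = 1,
                         noise_sd = 0.05,
                         fs = 1000, duration = 20, seed = 1L) {
  stopifnot(length(room) == 2L, all(room > 0),
            length(tx_pos) == 2L, length(rx_pos) == 2L,
            length(motion_pos) == 2L,
            noise_sd >= 0, duration > 0, fs > 0, reflection_gain > 0)
  inside <- function(p) all(p >= 0) && p[1] <= room[1] && p[2] <= room[2]
  if (!inside(tx_pos) || !inside(rx_pos) || !inside(motion_pos))
    stop("tx_pos, rx_pos and motion_pos must lie inside the room",
         call. = FALSE)
  n_subcarriers <- as.integer(n_subcarriers)
  if (n_subcarriers %% 30L != 0L)
    stop("n_subcarriers must be a multiple of 30", call. = FALSE)
  if (is.null(static_gain)) {
    static_gain <- 20 * exp(1i * 2 * pi * seq_len(n_subcarriers) /
                              n_subcarriers)
  }
  static_gain <- rep_len(static_gain, n_subcarriers)
  structure(list(room = room, tx_pos = tx_pos, rx_pos = rx_pos,
                 motion_pos = motion_pos, carrier_freq = carrier_freq,
                 subcarrier_spacing = subcarrier_spacing,
                 n_subcarriers = n_subcarriers, static_gain = static_gain,
                 reflection_gain = reflection_gain, noise_sd = noise_sd,
                 fs = fs, duration = duration, seed = as.integer(seed)),
            class = "scene_config")
}

#' Motion profile for the synthetic CSI simulator
#'
#' The three motion types mirror the reference experiments: a steel ruler
#' released with a 10 cm initial deflection that rings down (damped
#' sinusoid at 3.46 Hz), index-finger-to-thumb tapping at about 1 Hz with
#' roughly 8 cm displacement, and a resting-tremor surrogate whose
#' per-cycle frequency is drawn uniformly from 3-6 Hz with 8-10 cm hand
#' fluctuation.  The default timeline is a 5 s static lead-in followed by
#' 10 s of motion within a 20 s recording.
#'
#' @param motion_type `"ruler_vibration"`, `"finger_tapping"` or
#'   `"resting_tremor"`.
#' @param start motion onset time (s).
#' @param active_duration length of the active bout (s).
#' @param displacement_amplitude peak displacement (m); defaults are
#'   0.10 (ruler), 0.08 (tapping), 0.09 (tremor).
#' @param frequency_spec a single frequency in Hz, or `c(f_lo, f_hi)` for
#'   a per-cycle uniform draw; defaults are 3.46 Hz (ruler), 1 Hz
#'   (tapping), `c(3, 6)` Hz (tremor).
#' @param damping exponential decay rate (1/s), ruler only.
#' @param direction unit 2-vector of the motion direction, or `NULL` to
#'   move along the reflection-path gradient (the direction the link is
#'   most sensitive to).
#' @return An object of class `motion_profile`.
#' @export
motion_profile <- function(motion_type = c("resting_tremor",
                                           "finger_tapping",
                                           "ruler_vibration"),
                           start = 5, active_duration = 10,
                           displacement_amplitude = NULL,
                           frequency_spec = NULL,
                           damping = 0.35,
                           direction = NULL) {
  motion_type <- match.arg(motion_type)
  if (is.null(displacement_amplitude))
    displacement_amplitude <- switch(motion_type,
                                     ruler_vibration = 0.10,
                                     finger_tapping = 0.08,
                                     resting_tremor = 0.09)
  if (is.null(frequency_spec))
    frequency_spec <- switch(motion_type,
                             ruler_vibration = 3.46,
                             finger_tapping = 1,
                             resting_tremor = c(3, 6))
  stopifnot(start >= 0, active_duration > 0,
            displacement_amplitude >= 0,
            length(frequency_spec) %in% 1:2, all(frequency_spec > 0))
  if (!is.null(direction)) {
    stopifnot(length(direction) == 2L)
    direction <- direction / sqrt(sum(direction^2))
  }
  structure(list(motion_type = motion_type, start = start,
                 active_duration = active_duration,
                 displacement_amplitude = displacement_amplitude,
                 frequency_spec = frequency_spec, damping = damping,
                 direction = direction),
            class = "motion_profile")
}

#' Generate a displacement time series with ground truth
#'
#' Produces the scalar displacement (m) along the motion direction, zero
#' outside the active interval, together with the simulator's answer key:
#' the number of completed motion cycles, their peak times, the active
#' duration, and the mean frequency under the same fencepost convention
#' the pipeline estimator uses (`(count - 1) / span of cycle peaks`).
#'
#' * ruler: exponentially damped sinusoid;
#' * tapping: one raised-cosine pulse per cycle (strong impulse per tap);
#' * tremor: concatenated half-sine cycles, each full cycle's frequency
#'   drawn uniformly from the configured range.
#'
#' @param profile a [motion_profile()].
#' @param fs sampling rate (Hz).
#' @param duration total length (s); must cover `start + active_duration`.
#' @param seed integer seed (per-cycle frequency draws).
#' @return A list with `displacement` (length `round(fs * duration)`) and
#'   `ground_truth` (class `ground_truth`: `true_count`,
#'   `true_mean_frequency`, `true_duration`, `cycle_times`,
#'   `cycle_frequencies`).
#' @export
generate_displacement <- function(profile, fs, duration, seed = 1L) {
  stopifnot(inherits(profile, "motion_profile"), fs > 0, duration > 0)
  if (profile$start + profile$active_duration > duration + 1e-9)
    stop("motion extends past the end of the recording", call. = FALSE)
  if (max(profile$frequency_spec) >= fs / 2)
    stop("motion frequency at or above Nyquist (fs/2)", call. = FALSE)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1L) / fs
  disp <- numeric(n)
  amp <- profile$displacement_amplitude
  t0 <- profile$start
  Ta <- profile$active_duration
  cycle_times <- numeric(0)
  cycle_freqs <- numeric(0)

  if (amp > 0) {
    set.seed(as.integer(seed))
    f_rng <- range(profile$frequency_spec)
    draw_f <- function() if (f_rng[1L] == f_rng[2L]) f_rng[1L] else
      stats::runif(1L, f_rng[1L], f_rng[2L])
    if (profile$motion_type == "ruler_vibration") {
      f <- profile$frequency_spec[1L]
      act <- t >= t0 & t < t0 + Ta
      tau <- t[act] - t0
      disp[act] <- amp * exp(-profile$damping * tau) * sin(2 * pi * f * tau)
      n_cycles <- floor(Ta * f)
      if (n_cycles > 0) {
        k <- seq_len(n_cycles) - 1L
        cycle_times <- t0 + (k + 0.25) / f
        cycle_freqs <- rep(f, n_cycles)
      }
    } else {
      # tremor: concatenated full sine cycles; tapping: one raised-cosine
      # pulse (over the first 40% of the cycle) per cycle.  The frequency
      # is redrawn for every cycle when a range is configured.
      tapping <- profile$motion_type == "finger_tapping"
      tcur <- 0
      while (TRUE) {
        f <- draw_f()
        if (tcur + 1 / f > Ta + 1e-12) break
        tk <- t0 + tcur
        if (tapping) {
          width <- 0.4 / f
          i0 <- which(t >= tk & t < tk + width)
          disp[i0] <- amp * 0.5 * (1 - cos(2 * pi * (t[i0] - tk) / width))
          cycle_times <- c(cycle_times, tk + width / 2)
        } else {
          i0 <- which(t >= tk & t < tk + 1 / f)
          disp[i0] <- amp * sin(2 * pi * f * (t[i0] - tk))
          cycle_times <- c(cycle_times, tk + 1 / (4 * f))
        }
        cycle_freqs <- c(cycle_freqs, f)
        tcur <- tcur + 1 / f
      }
    }
  }
  count <- length(cycle_times)
  mean_f <- if (count >= 2L)
    (count - 1L) / (cycle_times[count] - cycle_times[1L]) else 0
  gt <- structure(list(true_count = count, true_mean_frequency = mean_f,
                       true_duration = Ta, cycle_times = cycle_times,
                       cycle_frequencies = cycle_freqs),
                  class = "ground_truth")
  list(displacement = disp, ground_truth = gt)
}

# gradient of the reflected path length d(p) = |tx - p| + |p - rx| at p
reflection_path_gradient <- function(tx, rx, p) {
  u1 <- (p - tx) / sqrt(sum((p - tx)^2))
  u2 <- (p - rx) / sqrt(sum((p - rx)^2))
  u1 + u2
}

#' Synthesize a CSI recording for a scene and motion profile
#'
#' Two fidelity modes:
#'
#' * `"geometric"` (default): per subcarrier `i`,
#'   `H(t, i) = static_gain(i) + g * exp(-2i*pi*d(t)/lambda_i)` where
#'   `d(t)` is the reflected path length transmitter -> moving point ->
#'   receiver and `lambda_i` the subcarrier wavelength.  Displacements of
#'   several wavelengths produce multiple amplitude fringes per motion
#'   cycle, as real captures do.
#' * `"direct"`: the subcarrier amplitude follows the displacement
#'   directly, `|H|(t, i) = |static_gain(i)| + depth_i * disp(t)/amp`,
#'   with per-subcarrier modulation depths (and random signs) drawn once
#'   from the seed.  One amplitude crest per motion cycle -- the mode to
#'   use when an exact analytic answer (cycle count) is wanted.
#'
#' Complex Gaussian noise of `scene$noise_sd` per component is added in
#' both modes.  The ground truth and generation parameters are stored in
#' `rec$meta`.
#'
#' @param scene a [scene_config()].
#' @param profile a [motion_profile()].
#' @param mode `"geometric"` or `"direct"`.
#' @return A [csi_recording()] with `meta$ground_truth`,
#'   `meta$static_gain`, `meta$seed`, `meta$mode`, `meta$active_index`.
#' @export
synthesize_csi <- function(scene, profile, mode = c("geometric", "direct")) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(profile, "motion_profile"))
  mode <- match.arg(mode)
  gd <- generate_displacement(profile, scene$fs, scene$duration,
                              seed = scene$seed)
  disp <- gd$displacement
  n <- length(disp)
  S <- scene$n_subcarriers
  set.seed(scene$seed + 1L)

  if (mode == "geometric") {
    dir <- profile$direction
    if (is.null(dir)) {
      g <- reflection_path_gradient(scene$tx_pos, scene$rx_pos,
                                    scene$motion_pos)
      dir <- g / sqrt(sum(g^2))
    }
    px <- scene$motion_pos[1L] + disp * dir[1L]
    py <- scene$motion_pos[2L] + disp * dir[2L]
    d <- sqrt((px - scene$tx_pos[1L])^2 + (py - scene$tx_pos[2L])^2) +
         sqrt((px - scene$rx_pos[1L])^2 + (py - scene$rx_pos[2L])^2)
    f_i <- scene$carrier_freq +
      (seq_len(S) - (S + 1) / 2) * scene$subcarrier_spacing
    lambda <- 299792458 / f_i
    H <- outer(d, 1 / lambda)                  # path length in wavelengths
    H <- scene$reflection_gain * exp(-2i * pi * H)
    H <- sweep(H, 2L, scene$static_gain, `+`)
  } else {
    depth <- scene$reflection_gain *
      stats::runif(S, 0.3, 1) * sample(c(-1, 1), S, replace = TRUE)
    rel <- if (profile$displacement_amplitude > 0)
      disp / profile$displacement_amplitude else disp
    A <- outer(rel, depth)
    A <- sweep(A, 2L, Mod(scene$static_gain), `+`)
    H <- A * exp(1i * outer(rep(1, n), Arg(scene$static_gain)))
  }
  if (scene$noise_sd > 0) {
    H <- H + complex(real = stats::rnorm(n * S, 0, scene$noise_sd),
                     imaginary = stats::rnorm(n * S, 0, scene$noise_sd))
    dim(H) <- c(n, S)
  }
  act <- which(disp != 0)
  active_index <- if (length(act)) c(min(act), max(act)) else integer(0)
  csi_recording(H, fs = scene$fs, carrier_freq = scene$carrier_freq,
                meta = list(ground_truth = gd$ground_truth,
                            static_gain = scene$static_gain,
                            seed = scene$seed, mode = mode,
                            profile = profile,
                            active_index = active_index))
}

#' Inject packet-loss artifacts
#'
#' Emulates the receiver logging the previous CSI value when a packet is
#' lost: each time step after the first is independently replaced, with
#' probability `rate`, by the previously *logged* row, so losses form
#' runs of identical rows (flat, horizontal stretches in the plots).
#'
#' @param rec a [csi_recording()].
#' @param rate per-sample loss probability in `[0, 1]`.
#' @param seed integer seed.
#' @return The recording with losses applied; `meta$packet_loss_index`
#'   records which time steps were overwritten.
#' @export
inject_packet_loss <- function(rec, rate, seed = 1L) {
  stopifnot(inherits(rec, "csi_recording"), rate >= 0, rate <= 1)
  n <- nrow(rec$samples)
  if (rate == 0 || n < 2L) {
    rec$meta$packet_loss_index <- integer(0)
    return(rec)
  }
  set.seed(as.integer(seed))
  lost <- which(stats::runif(n - 1L) < rate) + 1L
  for (i in lost) rec$samples[i, ] <- rec$samples[i - 1L, ]
  rec$meta$packet_loss_index <- lost
  rec
}

#' Inject a slow-response artifact
#'
#' Real links do not respond instantly to the start and end of motion:
#' the motion-induced CSI component fades in and out, producing smaller
#' waves at the boundaries of the active state.  The motion component
#' (samples minus the static background stored in
#' `meta$static_gain`) is multiplied by a trapezoidal envelope rising
#' linearly over `attack_time` from the motion onset and decaying
#' linearly over `release_time` into the motion offset.
#'
#' @param rec a [csi_recording()] produced by [synthesize_csi()].
#' @param attack_time,release_time ramp lengths (s), >= 0.
#' @return The modified recording.
#' @export
inject_slow_response <- function(rec, attack_time, release_time) {
  stopifnot(inherits(rec, "csi_recording"),
            attack_time >= 0, release_time >= 0)
  if (attack_time == 0 && release_time == 0) return(rec)
  if (is.null(rec$meta$static_gain) || !length(rec$meta$active_index))
    stop("recording lacks simulator metadata (static_gain/active_index); ",
         "slow response can only be injected into synthetic recordings",
         call. = FALSE)
  n <- nrow(rec$samples)
  i0 <- rec$meta$active_index[1L]; i1 <- rec$meta$active_index[2L]
  env <- rep(1, n)
  na <- round(attack_time * rec$fs); nr <- round(release_time * rec$fs)
  if (na > 0) {
    ramp <- seq(0, 1, length.out = na + 1L)[-(na + 1L)]
    idx <- i0:min(i0 + na - 1L, n)
    env[idx] <- ramp[seq_along(idx)]
  }
  if (nr > 0) {
    ramp <- seq(0, 1, length.out = nr + 1L)[-(nr + 1L)]
    idx <- i1:max(i1 - nr + 1L, 1L)
    env[idx] <- pmin(env[idx], ramp[seq_along(idx)])
  }
  motion <- sweep(rec$samples, 2L, rec$meta$static_gain, `-`)
  rec$samples <- sweep(motion * env, 2L, rec$meta$static_gain, `+`)
  rec$meta$slow_response <- c(attack = attack_time, release = release_time)
  rec
}

#' Generate a wearable-sensor-style reference trace
#'
#' Emulates the accelerometer worn during the reference measurements:
#' the acceleration along the motion direction, sampled at the sensor
#' rate (200 Hz), with additive Gaussian sensor noise.  The acceleration
#' is evaluated analytically cycle by cycle from the same ground truth
#' that drives [synthesize_csi()] (for the same seed), so its peaks
#' align with the motion cycles and the same peak-counting
#' quantification applies to it.
#'
#' @param profile a [motion_profile()].
#' @param duration total length (s).
#' @param fs_ref sensor sampling rate (Hz), default 200.
#' @param noise_sd sensor noise standard deviation (m/s^2).
#' @param seed integer seed (shared with [generate_displacement()] so the
#'   trace matches the CSI recording generated from the same seed).
#' @return A list of class `reference_trace`: `values` (m/s^2), `fs`,
#'   `axis`, `ground_truth`.
#' @export
generate_reference_trace <- function(profile, duration = 20, fs_ref = 200,
                                     noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(profile, "motion_profile"), fs_ref > 0)
  gd <- generate_displacement(profile, fs_ref, duration, seed = seed)
  gt <- gd$ground_truth
  n <- round(fs_ref * duration)
  t <- (seq_len(n) - 1L) / fs_ref
  acc <- numeric(n)
  amp <- profile$displacement_amplitude

  if (gt$true_count > 0 && amp > 0) {
    if (profile$motion_type == "ruler_vibration") {
      f <- profile$frequency_spec[1L]; w <- 2 * pi * f
      dmp <- profile$damping
      act <- t >= profile$start & t < profile$start + profile$active_duration
      tau <- t[act] - profile$start
      acc[act] <- amp * exp(-dmp * tau) *
        ((dmp^2 - w^2) * sin(w * tau) - 2 * dmp * w * cos(w * tau))
    } else if (profile$motion_type == "finger_tapping") {
      for (k in seq_len(gt$true_count)) {
        f <- gt$cycle_frequencies[k]
        width <- 0.4 / f
        tk <- gt$cycle_times[k] - width / 2
        idx <- which(t >= tk & t < tk + width)
        acc[idx] <- amp * 0.5 * (2 * pi / width)^2 *
          cos(2 * pi * (t[idx] - tk) / width)
      }
    } else {
      for (k in seq_len(gt$true_count)) {
        f <- gt$cycle_frequencies[k]
        tk <- gt$cycle_times[k] - 1 / (4 * f)
        idx <- which(t >= tk & t < tk + 1 / f)
        acc[idx] <- -amp * (2 * pi * f)^2 * sin(2 * pi * f * (t[idx] - tk))
      }
    }
  }
  set.seed(as.integer(seed) + 2L)
  if (noise_sd > 0) acc <- acc + stats::rnorm(n, 0, noise_sd)
  structure(list(values = acc, fs = fs_ref, axis = "motion-direction",
                 ground_truth = gt),
            class = "reference_trace")
}
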