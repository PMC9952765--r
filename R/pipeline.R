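#' Run the full quantification pipeline on a CSI recording
#'
#' Chains all stages: basic-signal extraction, Z-score normalization
#' (`P'`), Butterworth bandpass (`A`), SVD component selection (`V*'`),
#' short-time energy (`E`) and thresholding (`V_W`), Savitzky-Golay
#' smoothing (`Q`) and three-criterion peak counting -- and returns the
#' quantification together with every stage's output and parameters.
#'
#' @param rec a [csi_recording()].
#' @param motion_type `"resting_tremor"`, `"finger_tapping"` or
#'   `"ruler_vibration"`; sets the filter band and `f_max` via
#'   [band_preset()].
#' @param signal_kind which basic signal to analyse: `"amplitude"`
#'   (default), `"phase"`, `"phase_difference"` or `"ratio"`.
#' @param band,f_max override the preset filter band / peak `f_max`.
#' @param energy_window short-time energy window length (samples).
#' @param threshold_frac segmentation threshold as a fraction of
#'   `max(E)`.
#' @param savgol_window Savitzky-Golay window length (samples).
#' @param height_frac,prominence_frac peak height / prominence
#'   thresholds as fractions of `max(Q)`.
#' @param frequency_convention see [quantify_motion()].
#' @param streams for `"phase_difference"` / `"ratio"`: the two stream
#'   indices used.
#' @return A list of class `pipeline_result` with `quantification`
#'   (class `motion_quantification`; peak indices mapped back to
#'   recording coordinates), `segment`, `stages` (named list `P_prime`,
#'   `A`, `V_star`, `E`, `V_W`, `Q`), `packet_loss`, `params`.  For the
#'   ruler preset the duration is reported as `NA` (the decaying tail of
#'   the ring-down falls below the detectable range, so an end-of-motion
#'   time is not meaningful).
#' @export
quantify_recording <- function(rec,
                               motion_type = c("resting_tremor",
                                               "finger_tapping",
                                               "ruler_vibration"),
                               signal_kind = c("amplitude", "phase",
                                               "phase_difference", "ratio"),
                               band = NULL, f_max = NULL,
                               energy_window = 51L, threshold_frac = 0.1,
                               savgol_window = 101L,
                               height_frac = 0.2, prominence_frac = 0.3,
                               frequency_convention = "span",
                               streams = c(1L, 2L)) {
  stopifnot(inherits(rec, "csi_recording"))
  motion_type <- match.arg(motion_type)
  signal_kind <- match.arg(signal_kind)
  preset <- band_preset(motion_type)
  if (is.null(band)) band <- preset$band
  if (is.null(f_max)) f_max <- preset$f_max

  P <- switch(signal_kind,
              amplitude = extract_amplitude(rec),
              phase = extract_phase(rec),
              phase_difference = extract_phase_difference(rec, streams[1L],
                                                          streams[2L]),
              ratio = compute_csi_ratio(rec, streams[1L], streams[2L]))
  loss <- detect_packet_loss(rec)
  P_prime <- zscore_normalize(P)
  spec <- design_butterworth_bandpass(3L, band[1L], band[2L], rec$fs)
  A <- apply_filter(spec, P_prime)
  comp <- select_principal_component(A)
  E <- short_time_energy(comp, N = energy_window)
  seg <- segment_active(E, threshold_frac = threshold_frac,
                        merge_gap = round(rec$fs / band[1L]))
  crit <- peak_criteria(rec$fs, f_max, height_frac, prominence_frac)

  if (is.na(seg$start_index)) {
    quant <- quantify_motion(integer(0), seg)
    V_W <- numeric(0); Q <- numeric(0); peaks_abs <- integer(0)
  } else {
    V_W <- comp$series[seg$start_index:seg$end_index]
    m <- min(savgol_window, length(V_W) - (1 - length(V_W) %% 2))
    Q <- savgol_smooth(V_W, order = 3L, m = m)
    peaks <- find_motion_peaks(Q, crit)
    quant <- quantify_motion(peaks, seg,
                             frequency_convention = frequency_convention)
    peaks_abs <- as.integer(peaks) + seg$start_index - 1L
    quant$peak_indices <- peaks_abs
  }
  if (motion_type == "ruler_vibration") quant$duration <- NA_real_

  structure(list(
    quantification = quant, segment = seg,
    stages = list(P_prime = P_prime, A = A, V_star = comp, E = E,
                  V_W = V_W, Q = Q),
    packet_loss = loss,
    params = list(motion_type = motion_type, signal_kind = signal_kind,
                  band = band, f_max = f_max,
                  filter = list(b = spec$b, a = spec$a),
                  energy_window = energy_window,
                  threshold_frac = threshold_frac,
                  savgol_window = savgol_window,
                  height_frac = height_frac,
                  prominence_frac = prominence_frac,
                  min_separation = crit$min_separation,
                  frequency_convention = frequency_convention)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s / %s\n", x$params$motion_type,
              x$params$signal_kind))
  print(x$quantification)
  print(x$segment)
  if (nrow(x$packet_loss$ranges))
    cat(sprintf("  packet loss: %d flagged range(s), %.2f%% of samples\n",
                nrow(x$packet_loss$ranges),
                100 * x$packet_loss$flagged_fraction))
  invisible(x)
}

#' Serialize a pipeline result to a JSON report
#'
#' Writes the quantification, segment, peak indices, packet-loss flags
#' and every stage parameter (not the bulky stage series) to a JSON
#' file.
#'
#' @param result a `pipeline_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  q <- result$quantification
  rep <- list(
    quantification = list(count = q$count,
                          mean_frequency = q$mean_frequency,
                          duration = q$duration,
                          peak_indices = q$peak_indices,
                          prominences = q$prominences),
    segment = list(start_index = result$segment$start_index,
                   end_index = result$segment$end_index,
                   duration = result$segment$duration),
    packet_loss = list(ranges = result$packet_loss$ranges,
                       flagged_fraction = result$packet_loss$flagged_fraction),
    params = result$params)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
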