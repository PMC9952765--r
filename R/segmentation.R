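#' Short-time energy of the selected component
#'
#' `E_n = sum_{m = n-N+1}^{n} [V(m) w(n - m)]^2`: the energy in a
#' trailing window of `N` samples ending at `n`.  The default window is
#' rectangular, making `E` a trailing moving sum of squares; a Hamming
#' window is available.  Samples before index `N` use the available
#' prefix (truncated window, no padding), so `E` is defined for every
#' `n`.
#'
#' @param V a `component_selection` or numeric vector (`V*'`).
#' @param N window length in samples (odd, `1 < N <= length(V)`);
#'   default 51.
#' @param window `"rectangular"` or `"hamming"`.
#' @return A list of class `energy_series`: `E` (>= 0, length `T`), `N`,
#'   `window`, `fs`.
#' @export
short_time_energy <- function(V, N = 51L, window = c("rectangular",
                                                     "hamming")) {
  window <- match.arg(window)
  fs <- if (inherits(V, "component_selection")) V$fs else NA_real_
  x <- if (inherits(V, "component_selection")) V$series else as.numeric(V)
  N <- as.integer(N)
  Tn <- length(x)
  if (N > Tn) stop("window length N exceeds the series length",
                   call. = FALSE)
  if (N < 2L || N %% 2L == 0L) stop("N must be odd and > 1", call. = FALSE)
  w2 <- if (window == "rectangular") rep(1, N)
        else (0.54 - 0.46 * cos(2 * pi * (seq_len(N) - 1L) / (N - 1L)))^2
  # E = trailing convolution of x^2 with w^2 (w indexed by lag n - m)
  E <- as.numeric(stats::filter(x^2, w2, method = "convolution",
                                sides = 1L))
  # prefix: truncated windows
  for (n in seq_len(min(N - 1L, Tn)))
    E[n] <- sum(x[seq_len(n)]^2 * w2[n - seq_len(n) + 1L])
  structure(list(E = pmax(E, 0), N = N, window = window, fs = fs),
            class = "energy_series")
}

#' Threshold-based active/rest segmentation
#'
#' The active state is found from the energy series by basic
#' thresholding at `threshold_frac * max(E)`.  Above-threshold runs
#' separated by gaps shorter than `merge_gap` samples are merged, and
#' the longest merged run is returned (the experimental trials contain a
#' single active bout).  Set `all_segments = TRUE` to get every merged
#' run for multi-bout data.
#'
#' The short-time energy of an oscillation dips near every zero
#' crossing, so within a single bout the energy can sit below the
#' threshold for up to about half a period of the slowest in-band
#' motion.  `merge_gap` defaults to the energy window `N`, which is
#' adequate when the energy window spans a motion period; callers
#' filtering a known band should pass one period of the lower band edge
#' (`fs / f_l`), as [quantify_recording()] does.
#'
#' @param E an `energy_series` from [short_time_energy()].
#' @param threshold_frac fraction of `max(E)` used as the threshold
#'   (default 0.1).
#' @param fs sampling rate (Hz); defaults to the one carried by `E`.
#' @param merge_gap runs separated by fewer than this many
#'   below-threshold samples are merged (default `E$N`).
#' @param all_segments return all merged runs instead of the longest?
#' @return A `motion_segment` (list with 1-based inclusive
#'   `start_index`, `end_index`, `fs`, `duration`), an empty segment
#'   (`start_index = end_index = NA`, `duration = 0`) when nothing
#'   exceeds the threshold, or a list of `motion_segment`s when
#'   `all_segments = TRUE`.
#' @export
segment_active <- function(E, threshold_frac = 0.1, fs = NULL,
                           merge_gap = NULL, all_segments = FALSE) {
  stopifnot(inherits(E, "energy_series"))
  if (is.null(fs)) fs <- E$fs
  if (is.null(merge_gap)) merge_gap <- E$N
  e <- E$E
  empty <- structure(list(start_index = NA_integer_,
                          end_index = NA_integer_, fs = fs, duration = 0),
                     class = "motion_segment")
  if (!any(e > 0)) return(if (all_segments) list() else empty)
  thr <- threshold_frac * max(e)
  above <- e > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0L) return(if (all_segments) list() else empty)
  merged <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs) - 1L) + 1L) {
    if (runs[i, 1L] - merged[nrow(merged), 2L] - 1L < merge_gap)
      merged[nrow(merged), 2L] <- runs[i, 2L]
    else merged <- rbind(merged, runs[i, ])
  }
  as_seg <- function(row)
    structure(list(start_index = as.integer(row[1L]),
                   end_index = as.integer(row[2L]), fs = fs,
                   duration = (row[2L] - row[1L] + 1L) / fs),
              class = "motion_segment")
  if (all_segments)
    return(lapply(seq_len(nrow(merged)), function(i) as_seg(merged[i, ])))
  lens <- merged[, 2L] - merged[, 1L]
  as_seg(merged[which.max(lens), ])
}

#' @export
print.motion_segment <- function(x, ...) {
  if (is.na(x$start_index)) cat("<motion_segment> empty\n")
  else cat(sprintf("<motion_segment> [%d, %d] (%.3f s @ %g Hz)\n",
                   x$start_index, x$end_index, x$duration, x$fs))
  invisible(x)
}

#' Detect packet-loss runs in a recording
#'
#' Packet loss makes the receiver log the previous CSI row again, so
#' losses are maximal runs of consecutive identical rows.  Runs of at
#' least `min_run` rows are flagged; the flagged fraction is reported in
#' the result.
#'
#' @param rec a [csi_recording()].
#' @param min_run minimum run length (rows) to flag; default 3.
#' @return List with `ranges` (two-column matrix of 1-based inclusive
#'   row ranges), `flagged_fraction`, `min_run`.
#' @export
detect_packet_loss <- function(rec, min_run = 3L) {
  stopifnot(inherits(rec, "csi_recording"))
  n <- nrow(rec$samples)
  same <- rowSums(rec$samples[-1L, , drop = FALSE] !=
                  rec$samples[-n, , drop = FALSE]) == 0L
  ranges <- matrix(integer(0), 0L, 2L,
                   dimnames = list(NULL, c("start", "end")))
  if (n >= 2L && any(same)) {
    r <- rle(same)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      len <- r$lengths[i] + 1L            # rows in the identical run
      if (len >= min_run)
        ranges <- rbind(ranges, c(starts[i], ends[i] + 1L))
    }
  }
  flagged <- if (nrow(ranges)) sum(ranges[, 2L] - ranges[, 1L] + 1L) else 0L
  list(ranges = ranges, flagged_fraction = flagged / n,
       min_run = as.integer(min_run))
}
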