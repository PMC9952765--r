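#' Savitzky-Golay smoothing of the motion segment
#'
#' Least-squares polynomial smoothing, `Q(j) = sum_i C_i V_W(j + i)` over
#' a centred window, removes fake peaks before counting.  Order 3 with a
#' 101-sample window (0.1 s at 1000 Hz) preserves true crests of motions
#' up to ~10 Hz while flattening noise ripple.  Edges are handled by the
#' polynomial fit on the truncated first/last frames, so polynomials up
#' to the filter order are reproduced exactly everywhere.
#'
#' @param V_W numeric vector (the segmented component series).
#' @param order polynomial order (default 3).
#' @param m window length in samples (odd, `> order`, `<= length(V_W)`;
#'   default 101).
#' @return Smoothed numeric vector `Q`, same length as `V_W`.
#' @export
savgol_smooth <- function(V_W, order = 3L, m = 101L) {
  x <- as.numeric(V_W)
  m <- as.integer(m)
  if (m %% 2L == 0L || m <= order)
    stop("window length m must be odd and greater than the order",
         call. = FALSE)
  if (m > length(x))
    stop("segment (", length(x), " samples) shorter than the smoothing ",
         "window (", m, "); use a smaller window", call. = FALSE)
  as.numeric(signal::sgolayfilt(x, p = order, n = m))
}

#' Peak-finding criteria
#'
#' The three criteria that separate true motion crests from fake peaks:
#'
#' * minimum separation `floor(fs / f_max)` samples -- no two counted
#'   peaks closer than one period of the fastest expected motion
#'   (1000/10 Hz -> 100 samples for tapping, 1000/6 -> 166 for tremor);
#' * minimum height `0.2 * max(Q)`;
#' * minimum prominence `0.3 * max(Q)` (topographic prominence: height
#'   above the higher of the two flanking minima).
#'
#' @param fs sampling rate (Hz).
#' @param f_max highest expected motion frequency (Hz); from
#'   [band_preset()] for the standard motion types.
#' @param height_frac,prominence_frac fractions of `max(Q)` used for the
#'   height and prominence thresholds.
#' @return A list of class `peak_criteria`.
#' @export
peak_criteria <- function(fs, f_max, height_frac = 0.2,
                          prominence_frac = 0.3) {
  stopifnot(fs > 0, f_max > 0,
            height_frac > 0, height_frac < 1,
            prominence_frac > 0, prominence_frac < 1)
  min_sep <- max(1L, as.integer(floor(fs / f_max)))
  structure(list(min_separation = min_sep, f_max = f_max, fs = fs,
                 height_frac = height_frac,
                 prominence_frac = prominence_frac),
            class = "peak_criteria")
}

# topographic prominence of a local maximum at index i:
# extend left/right until a strictly higher sample or the series end;
# the reference level is the higher of the two interval minima.
peak_prominence <- function(x, i) {
  n <- length(x)
  lmin <- x[i]
  j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
  rmin <- x[i]
  j <- i + 1L
  while (j <= n && x[j] <= x[i]) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1L }
  x[i] - max(lmin, rmin)
}

#' Find motion peaks under the three criteria
#'
#' Candidate peaks are strict interior local maxima of `Q`.  Candidates
#' below the height or prominence thresholds are discarded; the
#' remaining ones are accepted greedily from highest to lowest (ties ->
#' earlier index), rejecting any candidate within `min_separation`
#' samples of an already accepted peak.
#'
#' @param Q numeric vector (smoothed motion segment).
#' @param criteria a [peak_criteria()].
#' @return Sorted integer vector of peak indices (1-based), with the
#'   per-peak prominences in attribute `"prominence"`.  If `max(Q) <= 0`
#'   no peaks are returned, with a warning.
#' @export
find_motion_peaks <- function(Q, criteria) {
  stopifnot(inherits(criteria, "peak_criteria"), length(Q) > 0L)
  x <- as.numeric(Q)
  if (max(x) <= 0) {
    warning("max(Q) <= 0: no positive crest to count")
    return(structure(integer(0), prominence = numeric(0)))
  }
  n <- length(x)
  cand <- which(x[-c(1L, n)] > x[-c(n - 1L, n)] &
                x[-c(1L, n)] > x[-c(1L, 2L)]) + 1L
  min_h <- criteria$height_frac * max(x)
  cand <- cand[x[cand] >= min_h]
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    keep <- prom >= criteria$prominence_frac * max(x)
    cand <- cand[keep]; prom <- prom[keep]
  } else prom <- numeric(0)
  if (length(cand) > 1L) {
    ord <- order(-x[cand], cand)          # highest first, tie -> earlier
    accepted <- integer(0)
    for (i in ord) {
      if (!length(accepted) ||
          all(abs(cand[i] - cand[accepted]) >= criteria$min_separation))
        accepted <- c(accepted, i)
    }
    o <- sort(accepted)
    cand <- cand[o]; prom <- prom[o]
  }
  structure(cand, prominence = prom)
}

#' Quantify motion from peaks and segment
#'
#' * `count`: number of accepted peaks (movement quantity);
#' * `duration`: segment length in seconds;
#' * `mean_frequency`: `(count - 1) / (span of peaks in seconds)` for
#'   two or more peaks, else 0.  The fencepost form uses only inter-peak
#'   spacing, so it is robust to slack in the segment boundaries; the
#'   alternative `count / duration` convention is available via
#'   `frequency_convention = "count_over_duration"`.
#'
#' @param peak_indices integer vector from [find_motion_peaks()]
#'   (indices are relative to the segment).
#' @param segment a `motion_segment` from [segment_active()].
#' @param fs sampling rate (Hz); defaults to the segment's.
#' @param frequency_convention `"span"` (default) or
#'   `"count_over_duration"`.
#' @return A list of class `motion_quantification`: `count`,
#'   `mean_frequency` (Hz), `duration` (s), `peak_indices`,
#'   `prominences`.
#' @export
quantify_motion <- function(peak_indices, segment, fs = NULL,
                            frequency_convention = c("span",
                                                     "count_over_duration")) {
  frequency_convention <- match.arg(frequency_convention)
  stopifnot(inherits(segment, "motion_segment"))
  if (is.null(fs)) fs <- segment$fs
  count <- length(peak_indices)
  mean_f <-
    if (count >= 2L && frequency_convention == "span")
      (count - 1L) / ((max(peak_indices) - min(peak_indices)) / fs)
    else if (count >= 1L && frequency_convention == "count_over_duration" &&
             segment$duration > 0)
      count / segment$duration
    else 0
  structure(list(count = count, mean_frequency = mean_f,
                 duration = segment$duration,
                 peak_indices = as.integer(peak_indices),
                 prominences = attr(peak_indices, "prominence")),
            class = "motion_quantification")
}

#' @export
print.motion_quantification <- function(x, ...) {
  cat(sprintf("<motion_quantification> count = %d, mean frequency = %.3f Hz, duration = %.3f s\n",
              x$count, x$mean_frequency, x$duration))
  invisible(x)
}

#' One-sided magnitude spectrum
#'
#' Frequency-domain check of the recovered motion: for resting tremor
#' the dominant energy should sit inside the 2-6 Hz band.
#'
#' @param series numeric vector (length >= 2).
#' @param fs sampling rate (Hz).
#' @return List with `frequency` (Hz, 0 .. fs/2) and `magnitude`.
#' @export
compute_spectrum <- function(series, fs) {
  x <- as.numeric(series)
  n <- length(x)
  stopifnot(n >= 2L, fs > 0)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1L)
  mag <- Mod(X[half]) / n
  mag[-c(1L, if (n %% 2L == 0L) length(half))] <-
    2 * mag[-c(1L, if (n %% 2L == 0L) length(half))]
  list(frequency = (half - 1L) * fs / n, magnitude = mag)
}
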