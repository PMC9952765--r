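#' Basic signal matrices derived from complex CSI
#'
#' The pipeline never works on complex CSI directly; it works on one of
#' four real-valued "basic signals": per-subcarrier amplitude, (sanitized)
#' phase, phase difference between two antenna streams, or the amplitude
#' ratio of two streams.  All four are `T x S'` real matrices sharing the
#' recording's time base.
#'
#' @param values real matrix `T x S'`.
#' @param kind one of `"amplitude"`, `"phase"`, `"phase_difference"`,
#'   `"ratio"`.
#' @param fs sampling rate (Hz).
#' @param source_streams provenance: which stream(s) produced each column.
#' @return An object of class `basic_signal`.
#' @keywords internal
basic_signal_matrix <- function(values, kind, fs, source_streams = NULL) {
  kind <- match.arg(kind,
                    c("amplitude", "phase", "phase_difference", "ratio"))
  structure(list(values = values, kind = kind, fs = fs,
                 source_streams = source_streams),
            class = "basic_signal")
}

#' @export
print.basic_signal <- function(x, ...) {
  cat(sprintf("<basic_signal: %s> %d x %d @ %g Hz\n", x$kind,
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

# wrap angles into (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Extract per-subcarrier CSI amplitude
#'
#' The amplitude `|H(i)|` is the modulus of each complex channel estimate:
#' it tracks the multipath-induced attenuation of each subcarrier and is
#' the default basic signal for motion quantification.
#'
#' @param rec a [csi_recording()].
#' @return A `basic_signal` of kind `"amplitude"` (values all >= 0).
#' @export
extract_amplitude <- function(rec) {
  stopifnot(inherits(rec, "csi_recording"))
  basic_signal_matrix(Mod(rec$samples), "amplitude", rec$fs,
                      source_streams = rec$streams)
}

#' Extract per-subcarrier CSI phase
#'
#' Raw CSI phase is corrupted by carrier frequency offset and sampling
#' frequency offset, which appear as a per-packet linear trend of phase
#' across subcarrier index plus a constant offset.  With `sanitize = TRUE`
#' (the default) that least-squares linear trend and the mean are removed
#' per time step and per antenna stream, leaving the motion-induced phase
#' residual; `sanitize = FALSE` returns the wrapped raw phase.
#'
#' @param rec a [csi_recording()].
#' @param sanitize remove the per-time-step across-subcarrier linear trend
#'   and mean offset (per stream)?
#' @return A `basic_signal` of kind `"phase"`, values wrapped to
#'   `(-pi, pi]`.  Zero-magnitude samples get phase 0 (a message reports
#'   how many).
#' @export
extract_phase <- function(rec, sanitize = TRUE) {
  stopifnot(inherits(rec, "csi_recording"))
  ph <- Arg(rec$samples)
  n_zero <- sum(rec$samples == 0)
  if (n_zero > 0) {
    ph[rec$samples == 0] <- 0
    message("extract_phase: ", n_zero,
            " zero-magnitude sample(s); phase set to 0")
  }
  ph <- wrap_phase(ph)
  if (isTRUE(sanitize)) {
    for (k in seq_len(nrow(rec$streams))) {
      cols <- stream_columns(rec, k)
      U <- unwrap_rows(ph[, cols, drop = FALSE])
      idx <- seq_along(cols)
      idxc <- idx - mean(idx)
      # per time step, least-squares line of phase vs subcarrier index
      slope <- as.vector(U %*% idxc) / sum(idxc^2)
      resid <- U - rowMeans(U) - outer(slope, idxc)
      ph[, cols] <- wrap_phase(resid)
    }
  }
  basic_signal_matrix(ph, "phase", rec$fs, source_streams = rec$streams)
}

# unwrap each row across columns (cumulative removal of 2*pi jumps)
unwrap_rows <- function(P) {
  n <- ncol(P)
  if (n < 2L) return(P)
  for (j in 2:n) {
    # P[, j - 1] is already unwrapped at this point
    k <- round((P[, j] - P[, j - 1L]) / (2 * pi))
    P[, j] <- P[, j] - 2 * pi * k
  }
  P
}

#' Phase difference between two antenna streams
#'
#' Computes the wrapped phase difference `arg(H_a(i)) - arg(H_b(i))` per
#' time step and subcarrier.  The difference between adjacent receive
#' antennas cancels the transmitter-side frequency offsets, so no further
#' sanitization is applied.
#'
#' @param rec a [csi_recording()].
#' @param stream_a,stream_b stream indices (defaults: the first two
#'   streams, i.e. receive antennas 1 and 2 of the same transmit antenna).
#' @return A `basic_signal` of kind `"phase_difference"` with 30 columns,
#'   wrapped to `(-pi, pi]`.  Identical stream indices give zeros with a
#'   warning.
#' @export
extract_phase_difference <- function(rec, stream_a = 1L, stream_b = 2L) {
  stopifnot(inherits(rec, "csi_recording"))
  ca <- stream_columns(rec, stream_a); cb <- stream_columns(rec, stream_b)
  if (stream_a == stream_b)
    warning("phase difference of a stream with itself is identically zero")
  d <- wrap_phase(Arg(rec$samples[, ca, drop = FALSE]) -
                  Arg(rec$samples[, cb, drop = FALSE]))
  basic_signal_matrix(d, "phase_difference", rec$fs,
                      source_streams = rec$streams[c(stream_a, stream_b), ])
}

#' Amplitude ratio of two antenna streams
#'
#' The CSI ratio `|H_a(i)| / |H_b(i)|` cancels amplitude noise common to
#' the two receive chains.  Denominator entries below
#' `eps = eps_factor * median(|H_b|)` are treated as invalid and imputed
#' from the nearest valid time step of the same subcarrier; the number of
#' imputed entries is reported via a message.
#'
#' @param rec a [csi_recording()].
#' @param stream_a,stream_b stream indices (numerator, denominator).
#' @param eps_factor fraction of the denominator stream's median amplitude
#'   below which a denominator is considered numerically zero.
#' @return A `basic_signal` of kind `"ratio"` (values >= 0).
#' @export
compute_csi_ratio <- function(rec, stream_a = 1L, stream_b = 2L,
                              eps_factor = 1e-6) {
  stopifnot(inherits(rec, "csi_recording"))
  a <- Mod(rec$samples[, stream_columns(rec, stream_a), drop = FALSE])
  b <- Mod(rec$samples[, stream_columns(rec, stream_b), drop = FALSE])
  eps <- eps_factor * stats::median(b)
  bad <- b <= eps
  r <- a / ifelse(bad, NA_real_, b)
  if (any(bad)) {
    message("compute_csi_ratio: ", sum(bad),
            " near-zero denominator entries imputed from nearest neighbor")
    for (j in which(colSums(bad) > 0L)) {
      col <- r[, j]
      ok <- which(!is.na(col))
      if (length(ok) == 0L)
        stop("column ", j, ": denominator stream is numerically zero ",
             "throughout; no valid neighbor to impute from", call. = FALSE)
      for (i in which(is.na(col)))
        col[i] <- col[ok[which.min(abs(ok - i))]]
      r[, j] <- col
    }
  }
  basic_signal_matrix(r, "ratio", rec$fs,
                      source_streams = rec$streams[c(stream_a, stream_b), ])
}
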