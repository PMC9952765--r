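#' Construct a CSI recording
#'
#' A CSI recording holds the complex channel estimates of one capture:
#' a `T x S` complex matrix (`T` time steps, `S` subcarriers), where the
#' `S` columns are grouped into antenna streams of 30 subcarriers each, in
#' the column order `(stream 1: subcarriers 1..30), (stream 2: ...), ...`.
#'
#' @param samples complex matrix, `T` time steps by `S` subcarriers.
#'   `S` must be a positive multiple of 30.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param streams data frame with columns `tx` and `rx` (antenna indices),
#'   one row per 30-subcarrier stream, or `NULL` to label streams
#'   `(tx = 1, rx = 1..n)` automatically.
#' @param carrier_freq carrier frequency in Hz (default 5 GHz band).
#' @param meta free-form list of provenance (scene geometry, seed,
#'   ground truth, ...).
#'
#' @return An object of class `csi_recording`.
#' @export
csi_recording <- function(samples, fs, streams = NULL, carrier_freq = 5e9,
                          meta = list()) {
  if (!is.matrix(samples) || nrow(samples) < 1L)
    stop("`samples` must be a matrix with at least one row", call. = FALSE)
  if (!is.complex(samples)) storage.mode(samples) <- "complex"
  S <- ncol(samples)
  if (S < 30L || S %% 30L != 0L)
    stop("number of subcarriers must be a positive multiple of 30, got ", S,
         call. = FALSE)
  if (anyNA(samples)) stop("`samples` contains NA entries", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  n_streams <- S %/% 30L
  if (is.null(streams)) {
    streams <- data.frame(tx = 1L, rx = seq_len(n_streams))
  }
  if (nrow(streams) != n_streams)
    stop("`streams` must have one row per 30-subcarrier group (",
         n_streams, "), got ", nrow(streams), call. = FALSE)
  structure(
    list(samples = samples, fs = fs, streams = streams,
         carrier_freq = carrier_freq, meta = meta),
    class = "csi_recording")
}

#' @export
print.csi_recording <- function(x, ...) {
  cat(sprintf("<csi_recording> %d time steps x %d subcarriers (%d streams)\n",
              nrow(x$samples), ncol(x$samples), nrow(x$streams)))
  cat(sprintf("  fs = %g Hz, carrier = %g GHz, duration = %.3f s\n",
              x$fs, x$carrier_freq / 1e9, nrow(x$samples) / x$fs))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Column indices of one antenna stream
#'
#' @param rec a [csi_recording()].
#' @param stream stream index (1-based row of `rec$streams`).
#' @return Integer vector of the 30 column indices of that stream.
#' @export
stream_columns <- function(rec, stream) {
  stopifnot(inherits(rec, "csi_recording"))
  n <- nrow(rec$streams)
  if (!is.numeric(stream) || length(stream) != 1L || stream < 1 || stream > n)
    stop("stream index must be in 1..", n, call. = FALSE)
  (as.integer(stream) - 1L) * 30L + seq_len(30L)
}

# make nested metadata JSON-safe: drop S3 classes and encode complex
# vectors as re/im pairs (restored by restore_meta on read)
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.complex(x)) return(list(re = Re(x), im = Im(x), .complex = TRUE))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

restore_meta <- function(x) {
  if (!is.list(x)) return(x)
  if (isTRUE(x$.complex)) return(complex(real = x$re, imaginary = x$im))
  lapply(x, restore_meta)
}

#' Write / read a CSI recording as CSV plus JSON metadata sidecar
#'
#' The CSV has a header `t, s1_re, s1_im, ..., sS_re, sS_im` and one row per
#' time step; `<prefix>.meta.json` stores `fs`, `streams`, `carrier_freq`
#' and `meta`.  A raw binary alternative ([write_csi_bin()]) exists for
#' large files.  Parsers for vendor capture formats (e.g. the Intel 5300
#' tool's `.dat`) are not provided; convert such captures to this CSV/JSON
#' pair (or the binary container) and they enter the pipeline unchanged.
#'
#' @param rec a [csi_recording()].
#' @param prefix output path prefix; files `<prefix>.csv` and
#'   `<prefix>.meta.json` are written.
#' @return `write_csi_csv` returns `prefix` invisibly; `read_csi_csv`
#'   returns a [csi_recording()].
#' @export
write_csi_csv <- function(rec, prefix) {
  stopifnot(inherits(rec, "csi_recording"))
  Tn <- nrow(rec$samples); S <- ncol(rec$samples)
  out <- matrix(0, Tn, 2L * S)
  out[, seq(1L, 2L * S, by = 2L)] <- Re(rec$samples)
  out[, seq(2L, 2L * S, by = 2L)] <- Im(rec$samples)
  df <- data.frame((seq_len(Tn) - 1L) / rec$fs, out)
  names(df) <- c("t", paste0("s", rep(seq_len(S), each = 2L),
                             c("_re", "_im")))
  utils::write.csv(df, paste0(prefix, ".csv"), row.names = FALSE)
  side <- list(fs = rec$fs, carrier_freq = rec$carrier_freq,
               streams = rec$streams, meta = strip_classes(rec$meta))
  jsonlite::write_json(side, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_csi_csv
#' @export
read_csi_csv <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
  side <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  re_cols <- grep("_re$", names(df)); im_cols <- grep("_im$", names(df))
  if (length(re_cols) != length(im_cols) || length(re_cols) == 0L)
    stop("malformed CSI CSV: expected paired s<k>_re / s<k>_im columns",
         call. = FALSE)
  samples <- as.matrix(df[re_cols]) + 1i * as.matrix(df[im_cols])
  dimnames(samples) <- NULL
  csi_recording(samples, fs = side$fs,
                streams = as.data.frame(side$streams),
                carrier_freq = side$carrier_freq,
                meta = if (is.null(side$meta)) list() else restore_meta(side$meta))
}

#' Raw binary CSI container
#'
#' Fixed layout, little-endian: the magic bytes `"CSIM"`, then three int32
#' (`T`, `S`, reserved 0) and one float64 (`fs`), then `T*S` interleaved
#' float64 pairs (re, im) in row-major order.  Stream labels, carrier
#' frequency and metadata travel in the same `<prefix>.meta.json` sidecar
#' as the CSV form.
#'
#' @inheritParams write_csi_csv
#' @return `write_csi_bin` returns `prefix` invisibly; `read_csi_bin` a
#'   [csi_recording()].
#' @export
write_csi_bin <- function(rec, prefix) {
  stopifnot(inherits(rec, "csi_recording"))
  con <- file(paste0(prefix, ".bin"), "wb"); on.exit(close(con))
  writeBin(charToRaw("CSIM"), con)
  writeBin(c(nrow(rec$samples), ncol(rec$samples), 0L), con,
           size = 4L, endian = "little")
  writeBin(rec$fs, con, size = 8L, endian = "little")
  inter <- rbind(as.vector(Re(t(rec$samples))), as.vector(Im(t(rec$samples))))
  writeBin(as.vector(inter), con, size = 8L, endian = "little")
  side <- list(fs = rec$fs, carrier_freq = rec$carrier_freq,
               streams = rec$streams, meta = strip_classes(rec$meta))
  jsonlite::write_json(side, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_csi_bin
#' @export
read_csi_bin <- function(prefix) {
  con <- file(paste0(prefix, ".bin"), "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "CSIM")) stop("not a CSIM binary file", call. = FALSE)
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  fs <- readBin(con, "double", 1L, size = 8L, endian = "little")
  v <- readBin(con, "double", 2L * hdr[1L] * hdr[2L], size = 8L,
               endian = "little")
  re <- v[seq(1L, length(v), by = 2L)]; im <- v[seq(2L, length(v), by = 2L)]
  samples <- matrix(re + 1i * im, nrow = hdr[1L], ncol = hdr[2L], byrow = TRUE)
  side <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  csi_recording(samples, fs = fs, streams = as.data.frame(side$streams),
                carrier_freq = side$carrier_freq,
                meta = if (is.null(side$meta)) list() else restore_meta(side$meta))
}
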