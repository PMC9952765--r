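#' Mean absolute relative error and accuracy
#'
#' For repeated trials, `e = mean(|q_i - g_i| / g_i) * 100` compares the
#' quantities estimated from CSI (`q`) against the reference-sensor
#' ground truth (`g`); the reported accuracy is `100 - e` (percent).
#'
#' @param q numeric vector of estimates.
#' @param g numeric vector of reference values (same length, no zeros).
#' @return A list of class `accuracy_report`: `q`, `g`, `e` (%),
#'   `accuracy` (%), `n_reps`.
#' @export
error_percentage <- function(q, g) {
  if (length(q) != length(g))
    stop("q and g must have equal length", call. = FALSE)
  if (any(g == 0))
    stop("reference value g = 0: relative error undefined", call. = FALSE)
  e <- mean(abs(q - g) / abs(g)) * 100
  structure(list(q = q, g = g, e = e, accuracy = 100 - e,
                 n_reps = length(q)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> n = %d, error = %.2f%%, accuracy = %.2f%%\n",
              x$n_reps, x$e, x$accuracy))
  invisible(x)
}

#' Quantify a wearable-sensor reference trace
#'
#' Applies the same smoothing + three-criterion peak counting used on
#' CSI data to the accelerometer-style reference trace, at the sensor
#' rate.  The minimum peak separation is `floor(fs_ref / f_max)`
#' (33 samples for tremor at 200 Hz), and the smoothing window covers
#' the same 0.1 s span as the CSI-rate default (21 samples at 200 Hz).
#'
#' @param trace a `reference_trace` from [generate_reference_trace()]
#'   (or any list with `values` and `fs`).
#' @param f_max highest expected motion frequency (Hz).
#' @param f_min slowest expected motion frequency (Hz, default 1); sets
#'   the segmentation merge gap to one motion period.
#' @param savgol_window smoothing window (samples); default scales the
#'   0.1 s span to the trace rate.
#' @return A `motion_quantification` (duration taken from the
#'   above-threshold active segment of the trace's energy).
#' @export
quantify_reference <- function(trace, f_max, f_min = 1,
                               savgol_window = NULL) {
  stopifnot(!is.null(trace$values), !is.null(trace$fs))
  x <- as.numeric(trace$values)
  fs <- trace$fs
  if (is.null(savgol_window)) {
    savgol_window <- round(0.1 * fs)
    if (savgol_window %% 2L == 0L) savgol_window <- savgol_window + 1L
  }
  sdev <- sqrt(mean(x^2) - mean(x)^2)
  if (sdev == 0) {
    seg <- structure(list(start_index = NA_integer_,
                          end_index = NA_integer_, fs = fs, duration = 0),
                     class = "motion_segment")
    return(quantify_motion(integer(0), seg))
  }
  xn <- (x - mean(x)) / sdev
  N <- round(0.051 * fs); if (N %% 2L == 0L) N <- N + 1L
  E <- short_time_energy(xn, N = max(3L, N))
  E$fs <- fs
  seg <- segment_active(E, fs = fs, merge_gap = round(fs / f_min))
  if (is.na(seg$start_index)) return(quantify_motion(integer(0), seg))
  V_W <- xn[seg$start_index:seg$end_index]
  m <- min(savgol_window, length(V_W) - (1 - length(V_W) %% 2))
  Q <- savgol_smooth(V_W, order = 3L, m = m)
  crit <- peak_criteria(fs, f_max)
  peaks <- find_motion_peaks(Q, crit)
  quantify_motion(peaks, seg)
}

#' Ordinary least-squares fit of accuracy versus distance
#'
#' Linear model `accuracy = slope * d + intercept` describing how the
#' sensing accuracy decays as the motion moves away from the line of
#' sight.
#'
#' @param d distances (m), at least 3 values, not all equal.
#' @param a accuracies (%) at those distances.
#' @return A list of class `distance_fit`: `slope` (%/m), `intercept`
#'   (%), `r_squared`, `model` (the underlying `lm`).
#' @export
fit_accuracy_vs_distance <- function(d, a) {
  if (length(d) < 3L || length(d) != length(a))
    stop("need >= 3 (distance, accuracy) pairs", call. = FALSE)
  if (diff(range(d)) == 0)
    stop("distances are all equal: slope undefined", call. = FALSE)
  fit <- stats::lm(a ~ d)
  ss_tot <- sum((a - mean(a))^2)
  r2 <- if (ss_tot > length(a) * .Machine$double.eps * max(1, mean(a)^2))
    1 - sum(stats::residuals(fit)^2) / ss_tot else 0
  r2 <- min(max(r2, 0), 1)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, model = fit),
            class = "distance_fit")
}

#' @export
print.distance_fit <- function(x, ...) {
  cat(sprintf("<distance_fit> accuracy = %.3f * d + %.3f  (R^2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Interpolated, symmetry-mapped accuracy contour
#'
#' Builds a sensing-accuracy surface from measurements on one half of
#' the room and mirrors it across the symmetry axis of the Fresnel
#' zone(s) (the centreline of the line of sight).  The measured points
#' must lie on a rectangular grid (as in a gridded room survey, here
#' with possibly missing nodes); values between nodes are obtained by
#' bilinear interpolation.  Queries outside the measured rectangle, or
#' in cells touching a missing node, return `NA` -- never an
#' extrapolation.
#'
#' @param points data frame with columns `x`, `y` (m) and `accuracy`
#'   (%), at least 3 non-collinear points.
#' @param axis the mirror axis: `list(type = "vertical", at = x0)` or
#'   `list(type = "horizontal", at = y0)`.
#' @param validation optional data frame (`x`, `y`, `accuracy`) of
#'   points measured on the *mirrored* side; their discrepancy
#'   `|measured - mirrored prediction|` is reported.
#' @return A list of class `contour_model` with `predict(xp, yp)`,
#'   `grid_x`, `grid_y`, `grid_z`, `axis`, and `validation` (input
#'   columns plus `predicted` and `discrepancy`).
#' @export
build_accuracy_contour <- function(points, axis = list(type = "vertical",
                                                       at = 0),
                                   validation = NULL) {
  stopifnot(is.data.frame(points),
            all(c("x", "y", "accuracy") %in% names(points)))
  if (nrow(points) < 3L)
    stop("need at least 3 measured points", call. = FALSE)
  if (diff(range(points$x)) == 0 || diff(range(points$y)) == 0)
    stop("measured points are collinear", call. = FALSE)
  if (!axis$type %in% c("vertical", "horizontal"))
    stop('axis$type must be "vertical" or "horizontal"', call. = FALSE)
  gx <- sort(unique(points$x))
  gy <- sort(unique(points$y))
  Z <- matrix(NA_real_, length(gy), length(gx))   # rows = y, cols = x
  for (i in seq_len(nrow(points)))
    Z[match(points$y[i], gy), match(points$x[i], gx)] <- points$accuracy[i]

  mirror <- function(xp, yp) {
    if (axis$type == "vertical") list(x = 2 * axis$at - xp, y = yp)
    else list(x = xp, y = 2 * axis$at - yp)
  }
  # reflect a query on the far side of the axis into the measured half
  fold <- function(xp, yp) {
    v <- if (axis$type == "vertical") xp else yp
    lo <- min(if (axis$type == "vertical") gx else gy)
    hi <- max(if (axis$type == "vertical") gx else gy)
    # the measured half is the side of the axis the grid lies on
    side <- if (abs(lo - axis$at) >= abs(hi - axis$at)) -1 else 1
    far <- if (side < 0) v > axis$at else v < axis$at
    m <- mirror(xp, yp)
    list(x = ifelse(axis$type == "vertical" & far, m$x, xp),
         y = ifelse(axis$type == "horizontal" & far, m$y, yp))
  }
  predict_fun <- function(xp, yp) {
    p <- fold(xp, yp)
    inside <- p$x >= min(gx) & p$x <= max(gx) &
              p$y >= min(gy) & p$y <= max(gy)
    out <- rep(NA_real_, length(xp))
    if (any(inside))
      out[inside] <- pracma::interp2(gx, gy, Z, p$x[inside], p$y[inside],
                                     method = "linear")
    out
  }
  val <- NULL
  if (!is.null(validation)) {
    val <- validation
    val$predicted <- predict_fun(val$x, val$y)
    val$discrepancy <- abs(val$accuracy - val$predicted)
  }
  structure(list(predict = predict_fun, grid_x = gx, grid_y = gy,
                 grid_z = Z, axis = axis, validation = val),
            class = "contour_model")
}

#' Export a contour model as a dense grid
#'
#' @param model a `contour_model`.
#' @param nx,ny grid resolution over the full (mirrored) extent.
#' @return Data frame with columns `x`, `y`, `accuracy` (`NA` outside
#'   the measured/mirrored region).
#' @export
contour_grid <- function(model, nx = 50L, ny = 50L) {
  stopifnot(inherits(model, "contour_model"))
  rx <- range(model$grid_x); ry <- range(model$grid_y)
  if (model$axis$type == "vertical")
    rx <- range(c(rx, 2 * model$axis$at - rx))
  else
    ry <- range(c(ry, 2 * model$axis$at - ry))
  xs <- seq(rx[1L], rx[2L], length.out = nx)
  ys <- seq(ry[1L], ry[2L], length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  g$accuracy <- model$predict(g$x, g$y)
  g
}
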