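#' Select the principal component that best represents the motion
#'
#' Of the 180 filtered subcarrier series only some respond to the target
#' motion.  The filtered matrix `A` is mean-centred by column and
#' decomposed by SVD, `A = U S V^T`; the candidate component time series
#' are the projection scores `A v_k` (length `T`), and the one with the
#' largest variance -- the leading component -- is selected.  Its sign is
#' fixed so that the series' sample skewness is nonnegative (peaks point
#' up; the SVD sign is arbitrary), and it is z-score renormalized.
#'
#' In multi-link mode simply concatenate all links' subcarrier columns
#' into one matrix before calling; all columns are decomposed together.
#' A per-link subcarrier pre-selection hook (`column_filter`) exists but
#' is off by default.
#'
#' @param A a `normalized_sequence` (stage `"A"`) or numeric matrix,
#'   `T x S`.
#' @param column_filter optional function `matrix -> logical vector`
#'   choosing which columns enter the decomposition.
#' @return A list of class `component_selection`: `series` (`V*'`, length
#'   `T`, mean 0, unit population sd), `component_index`,
#'   `singular_values` (nonincreasing), `explained_variation` (variance
#'   of each projection score), `dropped_columns`, `fs`.
#' @export
select_principal_component <- function(A, column_filter = NULL) {
  fs <- if (inherits(A, "normalized_sequence")) A$fs else NA_real_
  X <- if (inherits(A, "normalized_sequence")) A$values else as.matrix(A)
  Tn <- nrow(X)
  if (!is.null(column_filter)) {
    keep <- column_filter(X)
    X <- X[, keep, drop = FALSE]
  }
  v <- colMeans(X^2) - colMeans(X)^2
  dropped <- which(v <= .Machine$double.eps)
  if (length(dropped) == ncol(X) || all(!is.finite(v)))
    stop("no signal: all columns have zero variance", call. = FALSE)
  if (length(dropped)) {
    warning(length(dropped), " zero-variance column(s) dropped before SVD")
    X <- X[, -dropped, drop = FALSE]
  }
  Xc <- sweep(X, 2L, colMeans(X), `-`)
  sv <- svd(Xc, nu = 0L, nv = min(dim(Xc)))
  scores <- Xc %*% sv$v
  expl <- colMeans(scores^2)              # population variance; scores
  k <- which.max(expl)                    # are centred by construction
  s <- scores[, k]
  if (skewness_pop(s) < 0) s <- -s
  s <- (s - mean(s)) / sqrt(mean(s^2) - mean(s)^2)
  structure(list(series = s, component_index = k,
                 singular_values = sv$d,
                 explained_variation = expl,
                 dropped_columns = dropped, fs = fs),
            class = "component_selection")
}

skewness_pop <- function(x) {
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(0)
  mean(xc^3) / m2^1.5
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> component %d of %d, series length %d\n",
              x$component_index, length(x$explained_variation),
              length(x$series)))
  cat("  leading singular values:",
      format(utils::head(x$singular_values, 5L), digits = 4), "\n")
  invisible(x)
}
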