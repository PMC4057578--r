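#' Construct a spectrum on a period grid
#'
#' One spectral value per grid period, in units of the root-mean-square
#' ensemble power scaled by the square root of the segment count
#' (dimensionless once the input signal is normalized).  `time_index` is
#' the global sample index at which a streaming spectrum is valid; offline
#' block spectra leave it `NULL`.
#'
#' @param grid an [nse_grid].
#' @param values nonnegative numeric vector, one per grid period, ordered
#'   like `grid$periods` (i.e. by increasing frequency).
#' @param time_index optional integer sample counter.
#' @return An object of class `nse_spectrum`.
#' @export
nse_spectrum <- function(grid, values, time_index = NULL) {
  stopifnot(inherits(grid, "nse_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid$periods)) {
    stop("spectrum length must match grid length")
  }
  if (any(values < 0)) stop("spectral values must be nonnegative")
  structure(list(grid = grid, values = values, time_index = time_index),
            class = "nse_spectrum")
}

#' @export
print.nse_spectrum <- function(x, ...) {
  i <- which.max(x$values)
  cat(sprintf("<nse_spectrum> %d points, %.3f-%.3f Hz; peak %.4g at %.3f Hz%s\n",
              length(x$values), min(x$grid$frequencies), max(x$grid$frequencies),
              x$values[i], x$grid$frequencies[i],
              if (!is.null(x$time_index)) sprintf(" (k = %d)", x$time_index) else ""))
  invisible(x)
}

#' Rescale a spectrum to zero mean and unit variance
#'
#' Used when overlaying or pairing offline and streaming spectra: the
#' streaming estimator starts its moving averages from zero, so at any
#' finite sample count its spectrum carries a near-uniform attenuation
#' relative to the block estimate.  Standardizing both spectra (zero mean,
#' unit population variance) before comparison removes that common scale,
#' leaving only shape differences.  Because the shift makes some values
#' negative, the result is returned as a plain list, not an
#' `nse_spectrum`.
#'
#' @param s an [nse_spectrum] with non-constant values.
#' @return list with fields `grid`, `values` (standardized), `time_index`.
#' @export
standardize_spectrum <- function(s) {
  stopifnot(inherits(s, "nse_spectrum"))
  v <- s$values
  m <- mean(v)
  sdv <- sqrt(mean((v - m)^2))
  if (sdv <= 0) stop("degenerate spectrum: all values equal")
  list(grid = s$grid, values = (v - m) / sdv, time_index = s$time_index)
}

#' RMS difference between two spectra after min-max alignment
#'
#' Both spectra are min-max normalized to `[0, 1]` (the same profile
#' normalization used for the MP/SP parameters) and the root-mean-square
#' of their pointwise difference is returned.  This is the package's
#' offline-vs-streaming agreement measure; it is invariant to the common
#' positive affine scale differences the streaming warm-up introduces.
#'
#' @param a,b [nse_spectrum] objects (or standardized lists) on the same
#'   grid, each with non-constant values.
#' @return Nonnegative scalar; 0 means identical shapes.
#' @export
profile_rms <- function(a, b) {
  if (!identical(length(a$values), length(b$values))) {
    stop("spectra must share one grid")
  }
  mm <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) stop("degenerate spectrum: all values equal")
    (v - r[1]) / (r[2] - r[1])
  }
  sqrt(mean((mm(a$values) - mm(b$values))^2))
}

#' A set of spectra emitted over time on a shared grid
#'
#' Container used by [run_stream()] and [run_multichannel_stream()]:
#' a periods-by-emissions matrix of spectral values plus the sample index
#' of each emission.
#'
#' @param grid an [nse_grid].
#' @param values numeric matrix, `length(grid)` rows, one column per
#'   emitted spectrum.
#' @param time_index integer vector of emission sample counters, one per
#'   column.
#' @return An object of class `nse_spectrum_set`.
#' @export
nse_spectrum_set <- function(grid, values, time_index) {
  stopifnot(inherits(grid, "nse_grid"), is.matrix(values),
            nrow(values) == length(grid$periods),
            ncol(values) == length(time_index))
  structure(list(grid = grid, values = values,
                 time_index = as.integer(time_index)),
            class = "nse_spectrum_set")
}

#' @export
print.nse_spectrum_set <- function(x, ...) {
  cat(sprintf("<nse_spectrum_set> %d spectra of %d points, k = %d..%d\n",
              ncol(x$values), nrow(x$values),
              min(x$time_index), max(x$time_index)))
  invisible(x)
}

#' @export
length.nse_spectrum_set <- function(x) ncol(x$values)

#' Extract one spectrum from a spectrum set
#'
#' @param set an [nse_spectrum_set].
#' @param i emission index (column), `1..length(set)`.
#' @return An [nse_spectrum].
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "nse_spectrum_set"))
  i <- as.integer(i)
  if (i < 1L || i > ncol(set$values)) stop("spectrum index out of range")
  nse_spectrum(set$grid, set$values[, i], time_index = set$time_index[i])
}
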