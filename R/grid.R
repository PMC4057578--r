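#' Build the candidate-period grid for a frequency band
#'
#' The estimator scans integer segment lengths (periods) `w` rather than
#' frequency bins; each period maps to the frequency `f = rate / w`.  For a
#' band `[f_lo, f_hi]` the grid holds every integer from
#' `floor(rate / f_lo)` down to `floor(rate / f_hi)`.  Both endpoints use
#' the floor, so at 977 Hz the standard 3-12 Hz electrophysiologic band
#' yields w = 325 down to 81 - a 245-point spectrum - even though
#' 977/81 = 12.06 Hz slightly exceeds the nominal upper edge.
#'
#' Periods are stored in decreasing order, so `frequencies` is strictly
#' increasing.
#'
#' @param rate sample rate in Hz.
#' @param f_lo,f_hi band edges in Hz; `0 < f_lo < f_hi < rate / 2`.
#' @return An object of class `nse_grid` with fields `periods` (integer,
#'   decreasing), `frequencies` (`rate / periods`, increasing), `rate` and
#'   `band = c(f_lo, f_hi)`.
#' @examples
#' g <- build_period_grid(977, 3, 12)
#' length(g$periods)   # 245
#' range(g$periods)    # 81 325
#' @export
build_period_grid <- function(rate, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < rate / 2)) {
    stop("band must satisfy 0 < f_lo < f_hi < rate/2")
  }
  w_max <- floor(rate / f_lo)
  w_min <- floor(rate / f_hi)
  if (w_max < w_min || w_min < 1L) {
    stop(sprintf("band too narrow: no integer period between floor(rate/f_hi)=%d and floor(rate/f_lo)=%d",
                 w_min, w_max))
  }
  periods <- as.integer(seq.int(w_max, w_min))
  structure(
    list(periods = periods, frequencies = rate / periods,
         rate = as.numeric(rate), band = c(f_lo, f_hi)),
    class = "nse_grid"
  )
}

#' @export
print.nse_grid <- function(x, ...) {
  cat(sprintf("<nse_grid> %d periods, w = %d..%d (%.3f-%.3f Hz) @ %g Hz\n",
              length(x$periods), max(x$periods), min(x$periods),
              min(x$frequencies), max(x$frequencies), x$rate))
  invisible(x)
}

#' @export
length.nse_grid <- function(x) length(x$periods)

#' Number of whole segments of length w in a window of N samples
#'
#' `n = floor(N / w)`; the trailing `N - n * w` samples are discarded by
#' every operation that segments a window.
#'
#' @param N window length in samples.
#' @param w segment length (candidate period) in samples, `1 <= w <= N`.
#' @return Integer segment count, at least 1.
#' @examples
#' segment_count(8192, 81)   # 101
#' segment_count(8192, 325)  # 25
#' @export
segment_count <- function(N, w) {
  if (w < 1L) stop("segment length w must be >= 1")
  if (w > N) stop(sprintf("window too short: w = %d exceeds N = %d", w, N))
  as.integer(N %/% w)
}
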