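#' Construct a sampled signal
#'
#' A signal is a uniformly sampled real-valued sequence together with its
#' sample rate.  The `normalized` flag records that the sequence has been
#' standardized to zero mean and unit variance (population convention), the
#' preprocessing the spectral estimator assumes.
#'
#' @param samples numeric vector of sample values (arbitrary units,
#'   typically mV for bipolar electrograms).
#' @param rate sample rate in Hz; must be positive.
#' @param normalized logical; assert that `samples` already has zero mean
#'   and unit population variance.  Checked at construction.
#' @param channel optional channel label used in error messages.
#' @return An object of class `nse_signal` with fields `samples`, `rate`,
#'   `normalized` and `channel`.
#' @examples
#' s <- nse_signal(sin(2 * pi * 7 * seq(0, 2, by = 1 / 977)), rate = 977)
#' s <- normalize_signal(s)
#' @export
nse_signal <- function(samples, rate, normalized = FALSE, channel = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!is.finite(rate) || rate <= 0) stop("sample rate must be a positive number (Hz)")
  if (anyNA(samples)) stop("signal contains missing values")
  if (isTRUE(normalized)) {
    m <- mean(samples)
    v <- mean((samples - m)^2)
    if (abs(m) >= 1e-9 || abs(v - 1) >= 1e-6) {
      stop("normalized flag set but samples are not zero-mean / unit-variance")
    }
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         normalized = isTRUE(normalized), channel = channel),
    class = "nse_signal"
  )
}

#' @export
print.nse_signal <- function(x, ...) {
  cat(sprintf("<nse_signal> %d samples @ %g Hz (%.2f s)%s%s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (x$normalized) ", normalized" else "",
              if (!is.null(x$channel)) paste0(", channel ", x$channel) else ""))
  invisible(x)
}

#' @export
length.nse_signal <- function(x) length(x$samples)

#' Standardize a signal to zero mean and unit variance
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divisor = length, not length - 1), the convention used throughout the
#' estimator.  Idempotent: normalizing an already-normalized signal returns
#' it unchanged up to floating point.
#'
#' @param raw an [nse_signal] with at least two samples and non-zero
#'   variance.
#' @return The normalized [nse_signal] (rate preserved, `normalized` set).
#' @examples
#' normalize_signal(nse_signal(c(1, 3), rate = 100))$samples  # -1, 1
#' @export
normalize_signal <- function(raw) {
  stopifnot(inherits(raw, "nse_signal"))
  x <- raw$samples
  if (length(x) < 2L) stop("cannot normalize a signal with fewer than 2 samples")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) {
    stop(sprintf("degenerate signal%s: zero variance (constant input)",
                 if (!is.null(raw$channel)) paste0(" in channel ", raw$channel) else ""))
  }
  nse_signal((x - m) / sqrt(v), raw$rate, normalized = TRUE, channel = raw$channel)
}
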