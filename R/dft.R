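# Sliding-window DFT baseline and spectral-resolution calculators.  The
# DFT is deliberately recomputed in full at every window position (no
# incremental shortcuts): it is the comparison baseline, not the product.

#' DFT magnitude spectrum of the most recent window
#'
#' Computes the magnitude spectrum of the last `N` samples via the FFT
#' (power-of-two `N` only, matching a radix-2 implementation).  Magnitudes
#' are `Mod(X_k) / N` for bins `k = 0..N/2`; the absolute convention is
#' arbitrary — the baseline is used for shape and resolution comparison
#' only — but it is fixed and documented.
#'
#' @param x an [nse_signal] with `length(x) >= N`.
#' @param N window length in samples; must be a power of two.
#' @return List of class `nse_dft` with fields `frequencies`
#'   (`k * rate / N`, Hz), `magnitudes`, `N`, `rate`, `time_index` (index
#'   of the window's last sample).
#' @examples
#' x <- nse_signal(sin(2 * pi * 8 * (0:255) / 256), rate = 256)
#' d <- dft_power_spectrum(x, 256)
#' d$frequencies[which.max(d$magnitudes[-1]) + 1]  # 8 Hz
#' @export
dft_power_spectrum <- function(x, N) {
  stopifnot(inherits(x, "nse_signal"))
  N <- as.integer(N)
  if (N < 2L || bitwAnd(N, N - 1L) != 0L) {
    stop(sprintf("radix-2 window length must be a power of two (got %d)", N))
  }
  L <- length(x$samples)
  if (L < N) stop(sprintf("signal too short: %d samples < window N = %d", L, N))
  xs <- x$samples[(L - N + 1L):L]
  X <- fft(xs)
  k <- 0:(N %/% 2L)
  structure(list(frequencies = k * x$rate / N,
                 magnitudes = Mod(X[k + 1L]) / N,
                 N = N, rate = x$rate, time_index = L),
            class = "nse_dft")
}

#' @export
print.nse_dft <- function(x, ...) {
  cat(sprintf("<nse_dft> N = %d @ %g Hz, bin spacing %.4g Hz\n",
              x$N, x$rate, x$rate / x$N))
  invisible(x)
}

#' Sliding-window DFT spectra
#'
#' One full DFT recomputation per window position: windows start at
#' samples `1, 1 + M, 1 + 2M, ...` while they fit.  `M = 1` reproduces
#' the per-sample baseline used for head-to-head cost comparison with the
#' streaming estimator.
#'
#' @param x an [nse_signal] with `length(x) >= N`.
#' @param N window length (power of two).
#' @param M window advance in samples, `>= 1`.
#' @return List of `nse_dft` objects, one per window position.
#' @export
sliding_dft <- function(x, N, M = 1) {
  stopifnot(inherits(x, "nse_signal"))
  M <- as.integer(M)
  if (M < 1L) stop("moving size M must be >= 1")
  L <- length(x$samples)
  starts <- seq.int(1L, L - N + 1L, by = M)
  lapply(starts, function(s) {
    win <- nse_signal(x$samples[s:(s + N - 1L)], x$rate,
                      normalized = FALSE, channel = x$channel)
    d <- dft_power_spectrum(win, N)
    d$time_index <- s + N - 1L
    d
  })
}

#' DFT spectral resolution
#'
#' The DFT bin spacing `rate / N`: 0.122 Hz for an 8192-sample window at
#' 1 kHz.
#'
#' @param rate sample rate (Hz).
#' @param N window length (samples).
#' @return Resolution in Hz.
#' @export
dft_resolution <- function(rate, N) {
  stopifnot(rate > 0, N > 0)
  rate / N
}

#' Mean spectral resolution of a period grid
#'
#' The period-domain estimator's frequency spacing varies along the grid;
#' its mean resolution is `mean(rate / w^2)` over the grid periods —
#' about 0.037 Hz for the 3-12 Hz band at 1 kHz, more than 3 times finer
#' than the 0.122 Hz DFT bin spacing at the same window length.
#'
#' @param grid an [nse_grid].
#' @param rate optional sample rate (Hz) overriding `grid$rate`; the study
#'   quotes its resolution figures at a nominal 1 kHz over the period
#'   range derived at 977 Hz.
#' @return Mean resolution in Hz.
#' @export
nse_mean_resolution <- function(grid, rate = grid$rate) {
  stopifnot(inherits(grid, "nse_grid"))
  mean(rate / as.numeric(grid$periods)^2)
}

#' Number of DFT bins inside a band
#'
#' Counts integer bins `k` with `f_lo <= k * rate / N <= f_hi`; about 74
#' for 3-12 Hz with an 8192-point window at 1 kHz, versus 245 grid points
#' for the period-domain estimator on the same band.
#'
#' @param rate sample rate (Hz).
#' @param N window length (samples).
#' @param f_lo,f_hi band edges (Hz), below the Nyquist frequency.
#' @return Integer bin count (possibly zero).
#' @export
band_bin_count <- function(rate, N, f_lo, f_hi) {
  stopifnot(rate > 0, N > 0, f_lo <= f_hi, f_hi < rate / 2)
  k_lo <- ceiling(f_lo * N / rate)
  k_hi <- floor(f_hi * N / rate)
  max(0L, as.integer(k_hi - k_lo + 1L))
}
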