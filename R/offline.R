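# Offline (block) form of the estimator: segment the most recent window of
# N samples into n = floor(N/w) whole pieces of length w, average them
# position-wise, and take the scaled norm of the result.

# per-position sums over the n whole segments of length w (0-based phase j:
# sum_i x[i*w + j]); the trailing N - n*w samples are discarded
segment_sums <- function(x, w) {
  n <- length(x) %/% w
  rowSums(matrix(x[seq_len(n * w)], nrow = w))
}

#' Ensemble mean of consecutive signal segments
#'
#' Cuts the signal into `n = floor(N / w)` consecutive segments of length
#' `w` and averages them element-wise.  Correlated (periodic) segments
#' reinforce; incoherent content averages toward zero, which is the basis
#' of the period-domain spectrum.
#'
#' @param x a normalized [nse_signal].
#' @param w segment length in samples, `w <= length(x)`.
#' @return List of class `nse_ensemble_mean` with fields `w`, `values`
#'   (length-`w` mean vector), `n` (segment count).
#' @examples
#' x <- normalize_signal(nse_signal(rep(c(1, -1), 50), 100))
#' ensemble_mean(x, 2)$values
#' @export
ensemble_mean <- function(x, w) {
  stopifnot(inherits(x, "nse_signal"))
  if (!x$normalized) stop("ensemble_mean expects a normalized signal; call normalize_signal() first")
  n <- segment_count(length(x$samples), w)
  structure(list(w = as.integer(w), values = segment_sums(x$samples, w) / n, n = n),
            class = "nse_ensemble_mean")
}

#' Offline ensemble-average power spectrum
#'
#' For each candidate period `w` on the grid, the spectral value is the
#' Euclidean norm of the vector of per-position segment sums, scaled by
#' `1/sqrt(N)`:
#' \deqn{S_w = \frac{1}{\sqrt{N}} \left\| \sum_{i=1}^{n} x_{w,i} \right\|}
#' where the `x_{w,i}` are the `n = floor(N/w)` whole length-`w` segments
#' of the window.  This equals the root-mean-square ensemble power scaled
#' by `sqrt(n)` under the `n w ~ N` approximation; the `sqrt(n)` factor
#' flattens the white-noise baseline to ~1 across periods, so peaks are
#' directly comparable along the grid.  For unit-variance white noise the
#' expected squared value is `n w / N ~ 1`; for an exactly `w0`-periodic
#' unit-variance signal with `N = n w0`, `S_{w0} = sqrt(n) = sqrt(N / w0)`.
#'
#' `halved = TRUE` enables a redundancy-reduction path: for periods with
#' `2w` also on the grid, the segment-sum vector at `w` is formed by adding
#' the two halves of the (already computed) vector at `2w`.  This is exact
#' whenever `floor(N/w) = 2 floor(N/(2w))`; when `floor(N/w)` is odd the
#' halved path omits the final segment, a documented approximation, which
#' is why the direct path is the default and the reference.
#'
#' @param x a normalized [nse_signal] with `length(x) >= max(grid$periods)`.
#' @param grid an [nse_grid].
#' @return An [nse_spectrum].
#' @examples
#' g <- build_period_grid(100, 3, 12)
#' x <- normalize_signal(nse_signal(rep(sin(2 * pi * (1:20) / 20), 50), 100))
#' s <- nse_spectrum_offline(x, g)
#' @export
nse_spectrum_offline <- function(x, grid) {
  offline_spectrum_impl(x, grid, halved = FALSE)
}

#' @rdname nse_spectrum_offline
#' @export
nse_spectrum_offline_halved <- function(x, grid) {
  offline_spectrum_impl(x, grid, halved = TRUE)
}

offline_spectrum_impl <- function(x, grid, halved) {
  stopifnot(inherits(x, "nse_signal"), inherits(grid, "nse_grid"))
  if (!x$normalized) stop("spectrum expects a normalized signal; call normalize_signal() first")
  N <- length(x$samples)
  w_max <- max(grid$periods)
  if (N < w_max) {
    stop(sprintf("window too short: N = %d < largest period %d", N, w_max))
  }
  vals <- numeric(length(grid$periods))
  if (!halved) {
    for (i in seq_along(grid$periods)) {
      vals[i] <- sqrt(sum(segment_sums(x$samples, grid$periods[i])^2))
    }
  } else {
    # periods are stored in decreasing order, so the sum vector at 2w is
    # always available before w is reached
    sums <- vector("list", length(grid$periods))
    names(sums) <- as.character(grid$periods)
    for (i in seq_along(grid$periods)) {
      w <- grid$periods[i]
      key2 <- as.character(2L * w)
      s2 <- sums[[key2]]
      sums[[i]] <- if (!is.null(s2)) s2[seq_len(w)] + s2[w + seq_len(w)]
                   else segment_sums(x$samples, w)
      vals[i] <- sqrt(sum(sums[[i]]^2))
    }
  }
  nse_spectrum(grid, vals / sqrt(N))
}
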