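# Spectral parameters summarizing one spectrum: the dominant peak (DA,
# DF) and the mean/spread of the min-max normalized profile (MP, SP).
# A peaky, organized spectrum has large DA and small MP; a flat, noisy
# one has MP near 0.5.

#' Dominant frequency and amplitude of a spectrum
#'
#' The dominant frequency (DF) is the frequency of the largest spectral
#' value over the band covered by the grid, and the dominant amplitude
#' (DA) is that value.  Because the grid is confined to the 3-12 Hz
#' electrophysiologic band, harmonics of any DF above half the band's top
#' edge fall outside the grid, so the global band maximum is taken as the
#' fundamental.  Ties are broken toward the lowest frequency.
#'
#' @param s an [nse_spectrum] (or the list returned by
#'   [standardize_spectrum()]) with non-constant values.
#' @return List with fields `DF` (Hz) and `DA`.
#' @examples
#' g <- build_period_grid(100, 3, 12)
#' v <- numeric(length(g)); v[10] <- 2
#' dominant_peak(nse_spectrum(g, v))
#' @export
dominant_peak <- function(s) {
  v <- s$values
  if (diff(range(v)) == 0) stop("degenerate spectrum: all values equal")
  # frequencies are ascending, so which.max's first-match rule breaks
  # ties toward the lowest frequency
  i <- which.max(v)
  list(DF = s$grid$frequencies[i], DA = v[i])
}

#' Mean and spread of the normalized spectral profile
#'
#' The spectrum is min-max normalized to `[0, 1]`; MP is the mean of the
#' normalized profile and SP its population standard deviation.  Both are
#' invariant under positive affine rescaling of the spectrum, and no
#' peak-width or harmonic guestimates are involved.
#'
#' @param s an [nse_spectrum] (or standardized list) with
#'   `max(values) > min(values)`.
#' @return List with fields `MP` (in `[0, 1]`) and `SP` (`<= 0.5`).
#' @examples
#' g <- build_period_grid(100, 9, 12)  # 3-point grid
#' profile_stats(nse_spectrum(g, c(0, 1, 2)))  # MP 0.5, SP sqrt(1/6)
#' @export
profile_stats <- function(s) {
  v <- s$values
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) stop("degenerate spectrum: all values equal")
  p <- (v - rng[1]) / (rng[2] - rng[1])
  mp <- mean(p)
  list(MP = mp, SP = sqrt(mean((p - mp)^2)))
}

#' Extract all four spectral parameters
#'
#' Bundles [dominant_peak()] and [profile_stats()].
#'
#' @param s an [nse_spectrum] (or standardized list) with non-constant
#'   values.
#' @return List of class `nse_params` with fields `DA`, `DF`, `MP`, `SP`.
#' @export
extract_params <- function(s) {
  pk <- dominant_peak(s)
  pr <- profile_stats(s)
  structure(list(DA = pk$DA, DF = pk$DF, MP = pr$MP, SP = pr$SP),
            class = "nse_params")
}

#' @export
print.nse_params <- function(x, ...) {
  cat(sprintf("DA = %.4g, DF = %.3f Hz, MP = %.4f, SP = %.4f\n",
              x$DA, x$DF, x$MP, x$SP))
  invisible(x)
}

#' Parameter table for a set of spectra
#'
#' Vectorized parameter extraction over the columns of an
#' [nse_spectrum_set]; used for per-emission parameter logging during
#' streaming runs.
#'
#' @param set an [nse_spectrum_set]; columns with all-equal values yield
#'   `NA` parameters rather than an error.
#' @return data.frame with columns `time_index`, `DA`, `DF`, `MP`, `SP`.
#' @export
spectral_params <- function(set) {
  stopifnot(inherits(set, "nse_spectrum_set"))
  V <- set$values
  m <- ncol(V)
  cols <- seq_len(m)
  imax <- max.col(t(V), ties.method = "first")
  DA <- V[cbind(imax, cols)]
  mins <- V[cbind(max.col(t(-V), ties.method = "first"), cols)]
  rng <- DA - mins
  flat <- rng <= 0
  DF <- set$grid$frequencies[imax]
  rng_safe <- ifelse(flat, 1, rng)
  Pm <- sweep(sweep(V, 2, mins, "-"), 2, rng_safe, "/")
  MP <- colMeans(Pm)
  SP <- sqrt(colMeans(Pm^2) - MP^2)
  DA[flat] <- NA_real_; DF[flat] <- NA_real_
  MP[flat] <- NA_real_; SP[flat] <- NA_real_
  data.frame(time_index = set$time_index, DA = DA, DF = DF, MP = MP, SP = SP)
}
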