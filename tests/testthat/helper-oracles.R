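# Independent reference implementations used as oracles.  These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so the two routes to every number are independent.

# literal transcription of the ensemble-average spectrum: explicit double
# loop for the ensemble mean of each period, root-mean-square power, and
# the 1/sqrt(N) output scaling
naive_nse_spectrum <- function(samples, periods) {
  N <- length(samples)
  vapply(periods, function(w) {
    n <- floor(N / w)
    e <- numeric(w)
    for (j in 1:w) {
      acc <- 0
      for (i in 0:(n - 1)) acc <- acc + samples[i * w + j]
      e[j] <- acc / n
    }
    P <- sum(e * e) / w                  # root-mean-square ensemble power, squared
    n * sqrt(P * w) / sqrt(N)            # sqrt(n)-scaled RMS power, 1/sqrt(N) form
  }, numeric(1))
}

# the halved-path oracle needs the effective segment count actually used
# when sums are formed by recursive period doubling
halved_segments_used <- function(N, w, periods) {
  if ((2 * w) %in% periods) 2 * halved_segments_used(N, 2 * w, periods) else floor(N / w)
}

# scalar moving-average recursion applied to the subsampled series
# x[j], x[j + w], x[j + 2w], ... — the reference for one ring-buffer slot
ema_slot_oracle <- function(samples, w, j, N) {
  n <- floor(N / w)
  c1 <- (n - 1) / n
  c2 <- 1 / n
  y <- 0
  idx <- seq.int(j, length(samples), by = w)
  for (t in idx) y <- c1 * y + c2 * samples[t]
  y
}

# brute-force O(N^2) DFT magnitudes for bins 0..N/2, same 1/N convention
# as the package
naive_dft_magnitudes <- function(samples) {
  N <- length(samples)
  ks <- 0:(N %/% 2)
  vapply(ks, function(k) {
    re <- sum(samples * cos(-2 * pi * k * (0:(N - 1)) / N))
    im <- sum(samples * sin(-2 * pi * k * (0:(N - 1)) / N))
    sqrt(re^2 + im^2) / N
  }, numeric(1))
}

# loop-based per-position segment sums (test-local, independent of the
# package's vectorized internals)
segment_sums_for_test <- function(samples, w) {
  n <- floor(length(samples) / w)
  out <- numeric(w)
  for (j in 1:w) for (i in 0:(n - 1)) out[j] <- out[j] + samples[i * w + j]
  out
}

# local grid step (Hz) at the period holding frequency f
local_grid_step <- function(rate, f) {
  w <- floor(rate / f)
  rate / w - rate / (w + 1)
}

make_white_signal <- function(n, rate = 977, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  normalize_signal(nse_signal(rnorm(n), rate))
}
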