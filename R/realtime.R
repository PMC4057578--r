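# Streaming (real-time) form of the estimator.  Instead of re-averaging n
# segments per period for every window position, each period keeps a ring
# buffer of moving-average ensemble means; one new sample costs one
# read-modify-write per period plus a difference-of-squares power update,
# so a full spectrum is available after every input sample (moving size
# M = 1).

#' Moving-average constants for a period
#'
#' The streaming estimator replaces the block average of `n = floor(N/w)`
#' segments with a first-order recursion `e <- c1 * e + c2 * x` applied to
#' the ring-buffer slot each new sample lands on, with
#' `c1 = (n - 1) / n` and `c2 = 1 / n`.  The constants satisfy
#' `c1 + c2 * n = 1`, so a constant input is a fixed point.
#'
#' @param N analysis window length in samples.
#' @param w candidate period in samples, `1 <= w <= N`.
#' @return List with fields `n`, `c1`, `c2`.
#' @examples
#' moving_average_constants(8192, 81)   # n = 101
#' moving_average_constants(8192, 325)  # n = 25
#' @export
moving_average_constants <- function(N, w) {
  n <- segment_count(N, w)
  list(n = n, c1 = (n - 1) / n, c2 = 1 / n)
}

#' Configuration for the streaming estimator
#'
#' @param grid an [nse_grid] of candidate periods.
#' @param N analysis window length in samples (default 8192, about 8 s at
#'   977 Hz); sets the effective memory of the moving averages via
#'   `n = floor(N/w)` and the output scale `1/sqrt(N)`.
#' @param move_size spectra per input sample; the design point is one
#'   spectral update for every new sample, so only `1` is accepted.
#' @return List of class `nse_stream_config` with the precomputed `scale
#'   = 1/sqrt(N)`.
#' @export
stream_config <- function(grid, N = 8192, move_size = 1) {
  stopifnot(inherits(grid, "nse_grid"))
  if (move_size != 1) {
    stop("the streaming estimator updates once per input sample (move_size = 1)")
  }
  if (N < max(grid$periods)) {
    stop(sprintf("window N = %d is shorter than the largest period %d",
                 N, max(grid$periods)))
  }
  structure(list(grid = grid, N = as.integer(N), move_size = 1L,
                 scale = 1 / sqrt(N)),
            class = "nse_stream_config")
}

#' Initialize streaming state
#'
#' All ensemble-mean ring buffers and running powers start at zero and the
#' wrap indices are positioned so the first input sample lands on slot 1 of
#' every buffer.  Early spectra are therefore rough, attenuated estimates
#' that sharpen as the moving averages fill (callers wanting fully warmed
#' estimates can discard the first `N` emissions).
#'
#' @param config an [nse_stream_config].
#' @return An object of class `nse_stream_state`.
#' @export
stream_init <- function(config) {
  stopifnot(inherits(config, "nse_stream_config"))
  w <- config$grid$periods
  n <- config$N %/% w
  structure(list(
    config = config,
    e = numeric(sum(w)),
    offsets = as.integer(c(0L, cumsum(w))[seq_along(w)]),
    P = numeric(length(w)),
    ind = as.integer(w - 1L),   # next sample wraps to slot 0 (1-based slot 1)
    n = as.numeric(n),
    c1 = (n - 1) / n,
    c2 = 1 / n,
    k = 0
  ), class = "nse_stream_state")
}

#' @export
print.nse_stream_state <- function(x, ...) {
  cat(sprintf("<nse_stream_state> %d periods, N = %d, k = %d\n",
              length(x$P), x$config$N, as.integer(x$k)))
  invisible(x)
}

#' Advance the streaming state by one or more samples
#'
#' For every grid period and each input sample, the wrap index advances by
#' one (mod `w`), the slot it points to is rewritten with the moving
#' average `c1 * old + c2 * sample`, and the running power is adjusted by
#' the difference of squares.  Exactly one ring-buffer slot per period is
#' touched per sample.
#'
#' @param state an [nse_stream_state].
#' @param samples numeric vector of one or more finite input samples
#'   (pre-normalized, like the offline path).
#' @return The advanced [nse_stream_state] (value semantics: the input
#'   state is not modified).
#' @export
stream_update <- function(state, samples) {
  stopifnot(inherits(state, "nse_stream_state"))
  samples <- as.numeric(samples)
  if (length(samples) < 1L) return(state)
  res <- stream_advance_cpp(state$e, state$P, state$ind,
                            state$c1, state$c2, state$n,
                            state$config$grid$periods, state$offsets,
                            samples, state$k, state$config$scale, 0L)
  state$e <- res$e
  state$P <- res$P
  state$ind <- res$ind
  state$k <- res$k
  state
}

#' Read the current spectrum off a streaming state
#'
#' `S_w = n(w) * sqrt(max(P_w, 0)) / sqrt(N)`, the streaming analogue of
#' the offline spectral point.  Running powers that have drifted slightly
#' negative through floating-point cancellation are clamped at zero with a
#' warning.
#'
#' @param state an [nse_stream_state].
#' @return An [nse_spectrum] with `time_index = k`.
#' @export
stream_spectrum <- function(state) {
  stopifnot(inherits(state, "nse_stream_state"))
  P <- state$P
  if (any(P < -1e-9)) {
    warning("negative running power clamped to zero (floating-point drift)")
  }
  nse_spectrum(state$config$grid,
               state$n * sqrt(pmax(P, 0)) * state$config$scale,
               time_index = as.integer(state$k))
}

#' Stream a whole signal, emitting spectra along the way
#'
#' Applies the per-sample update to every sample of `x` and emits a
#' spectrum after every `emit_every`-th sample (`emit_every = 1` emits one
#' spectrum per sample, the real-time design point; larger values thin the
#' output without changing the computation, which is always per-sample).
#'
#' @param x a normalized [nse_signal].
#' @param config an [nse_stream_config] (grid rate should match the
#'   signal).
#' @param emit_every emission stride in samples.
#' @param state optional starting [nse_stream_state]; default fresh.
#' @return An [nse_spectrum_set]; the attribute `"final_state"` carries the
#'   state after the last sample.
#' @examples
#' g <- build_period_grid(100, 3, 12)
#' x <- normalize_signal(nse_signal(rep(sin(2 * pi * (1:20) / 20), 30), 100))
#' s <- run_stream(x, stream_config(g, N = 512), emit_every = length(x))
#' @export
run_stream <- function(x, config, emit_every = 1, state = NULL) {
  stopifnot(inherits(x, "nse_signal"), inherits(config, "nse_stream_config"))
  if (!x$normalized) stop("run_stream expects a normalized signal; call normalize_signal() first")
  emit_every <- as.integer(emit_every)
  if (emit_every < 1L || emit_every > length(x$samples)) {
    stop("emit_every must be between 1 and the signal length")
  }
  if (is.null(state)) state <- stream_init(config)
  res <- stream_advance_cpp(state$e, state$P, state$ind,
                            state$c1, state$c2, state$n,
                            config$grid$periods, state$offsets,
                            x$samples, state$k, config$scale, emit_every)
  if (res$clamped > 0) {
    warning(sprintf("%d negative running-power values clamped to zero (floating-point drift)",
                    res$clamped))
  }
  state$e <- res$e
  state$P <- res$P
  state$ind <- res$ind
  state$k <- res$k
  out <- nse_spectrum_set(config$grid, res$S, res$emit_k)
  attr(out, "final_state") <- state
  out
}
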