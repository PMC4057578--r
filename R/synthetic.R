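# Synthetic fractionated-electrogram generator.  Real atrial electrograms
# during fibrillation show repeating multiphasic activation complexes at a
# dominant rate in the 3-12 Hz band, with cycle-length jitter, beat-to-beat
# amplitude variation, broadband noise, sometimes a second competing
# periodicity (split spectral peaks) and rate changes over time.  The
# generator emulates exactly those features with known ground truth, so
# the whole pipeline can be exercised without clinical recordings.

#' Specification of a synthetic fractionated electrogram
#'
#' @param rate sample rate in Hz (default 977, the study's acquisition
#'   rate).
#' @param length record length in samples (default 16384, two 8192-sample
#'   analysis windows at ~8 s each).
#' @param df programmed dominant frequency in Hz, within 3-12; `NULL`
#'   generates a noise-only record (requires `noise_sd > 0`).
#' @param jitter_frac fractional cycle-length jitter: each activation lands
#'   at `nominal + (rate/df) * jitter_frac * z` with standard normal `z`
#'   (clamped to +/- 45% of a cycle), where the nominal firing times form a
#'   regular lattice at the programmed rate.  Consecutive intervals thus
#'   vary cycle to cycle while the long-run phase stays anchored, as for a
#'   driver-paced activation process.  Must be `< 0.5`.
#' @param complex_width_ms activation-complex duration in ms (default 100,
#'   representative of the prolonged multicomponent complexes that define
#'   fractionated electrograms); the complex is a biphasic
#'   derivative-of-Gaussian whose +/-3 sigma support spans this duration.
#'   Complexes much narrower than the cycle length behave like impulse
#'   trains, whose period-domain combs carry rational-ratio teeth
#'   comparable to the fundamental; the default reflects the sustained
#'   local activity the estimator is designed for.
#' @param amp_jitter fractional standard deviation of per-complex
#'   amplitude variation (default 0.1).
#' @param noise_sd additive white-noise standard deviation relative to the
#'   unit-power event train (so 0.5 means SNR = 4 in power).
#' @param secondary_df optional second periodicity in Hz (split peaks);
#'   `NULL` for none.
#' @param secondary_amp amplitude of the secondary train relative to the
#'   primary (default 0.5).
#' @param df_schedule optional data.frame with columns `at` (sample index,
#'   increasing) and `df` (Hz): the dominant frequency switches to `df` at
#'   sample `at`, emulating transient rate changes.  No transition
#'   smoothing is applied.
#' @param seed RNG seed for reproducibility; `NULL` uses the current RNG
#'   state.
#' @return List of class `nse_synthetic_spec`.
#' @export
synthetic_spec <- function(rate = 977, length = 16384, df = 7,
                           jitter_frac = 0.05, complex_width_ms = 100,
                           amp_jitter = 0.1, noise_sd = 0.5,
                           secondary_df = NULL, secondary_amp = 0.5,
                           df_schedule = NULL, seed = NULL) {
  spec <- structure(list(rate = rate, length = as.integer(length), df = df,
                         jitter_frac = jitter_frac,
                         complex_width_ms = complex_width_ms,
                         amp_jitter = amp_jitter, noise_sd = noise_sd,
                         secondary_df = secondary_df,
                         secondary_amp = secondary_amp,
                         df_schedule = df_schedule, seed = seed),
                    class = "nse_synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  bad <- character(0)
  if (!is.numeric(spec$rate) || spec$rate <= 0) bad <- c(bad, "rate must be positive")
  if (spec$length < 2L) bad <- c(bad, "length must be >= 2 samples")
  if (!is.null(spec$df)) {
    if (!(spec$df >= 3 && spec$df <= 12)) bad <- c(bad, "df must lie in [3, 12] Hz")
    else if (spec$length < 2 * spec$rate / spec$df) {
      bad <- c(bad, "length must cover at least two cycles (length >= 2*rate/df)")
    }
  } else if (!is.numeric(spec$noise_sd) || spec$noise_sd <= 0) {
    bad <- c(bad, "noise-only records (df = NULL) require noise_sd > 0")
  }
  if (!(spec$jitter_frac >= 0 && spec$jitter_frac < 0.5)) {
    bad <- c(bad, "jitter_frac must lie in [0, 0.5)")
  }
  if (spec$complex_width_ms <= 0) bad <- c(bad, "complex_width_ms must be positive")
  if (spec$amp_jitter < 0) bad <- c(bad, "amp_jitter must be >= 0")
  if (spec$noise_sd < 0) bad <- c(bad, "noise_sd must be >= 0")
  if (!is.null(spec$secondary_df) && !(spec$secondary_df >= 3 && spec$secondary_df <= 12)) {
    bad <- c(bad, "secondary_df must lie in [3, 12] Hz")
  }
  if (!is.null(spec$df_schedule)) {
    sch <- spec$df_schedule
    ok <- is.data.frame(sch) && all(c("at", "df") %in% names(sch)) &&
      !is.unsorted(sch$at, strictly = TRUE) &&
      all(sch$at >= 1 & sch$at <= spec$length) &&
      all(sch$df >= 3 & sch$df <= 12)
    if (!ok) {
      bad <- c(bad, "df_schedule must be a data.frame(at, df) with increasing in-range 'at' and df in [3, 12]")
    }
  }
  if (length(bad) > 0) {
    stop(paste0("invalid synthetic spec: ", paste(bad, collapse = "; ")))
  }
  invisible(spec)
}

# biphasic derivative-of-Gaussian activation complex, peak amplitude 1
activation_kernel <- function(rate, width_ms) {
  sigma <- width_ms / 1000 * rate / 6   # +/- 3 sigma spans the stated width
  half <- ceiling(4 * sigma)
  u <- (-half):half
  ker <- -(u / sigma) * exp(-u^2 / (2 * sigma^2))
  ker / max(abs(ker))
}

# dominant frequency in effect at sample s under a piecewise schedule
df_at <- function(spec, s) {
  df <- spec$df
  sch <- spec$df_schedule
  if (!is.null(sch)) {
    hit <- which(sch$at <= s)
    if (length(hit) > 0) df <- sch$df[max(hit)]
  }
  df
}

# Place jittered activation complexes.  Events are jittered around a
# regular lattice of nominal firing times (driver-paced timing): each
# complex lands at nominal + jitter_frac * period * z, with the offset
# clamped to +/- 0.45 period so events stay ordered.  Perturbing times
# rather than inter-event intervals keeps the long-run phase anchored to
# the programmed rate; accumulating interval jitter would random-walk the
# phase across the analysis window and no ensemble average could recover
# the rate.  Events start half a cycle in, so a jitter-free integer-period
# train is exactly periodic at sample level.
place_train <- function(spec, df0, amp, use_schedule = FALSE) {
  len <- spec$length
  ker <- activation_kernel(spec$rate, spec$complex_width_ms)
  half <- (length(ker) - 1L) %/% 2L
  y <- numeric(len)
  t <- spec$rate / df0 / 2
  while (round(t) <= len) {
    period <- spec$rate / if (use_schedule) df_at(spec, round(t)) else df0
    offs <- spec$jitter_frac * rnorm(1)
    centre <- round(t + period * max(-0.45, min(0.45, offs)))
    a <- amp * (1 + spec$amp_jitter * rnorm(1))
    lo <- centre - half
    hi <- centre + half
    klo <- max(1L, lo); khi <- min(len, hi)
    if (khi >= klo) {
      y[klo:khi] <- y[klo:khi] + a * ker[(klo - lo + 1L):(khi - lo + 1L)]
    }
    t <- t + period
  }
  y
}

#' Generate a synthetic fractionated electrogram
#'
#' Places biphasic activation complexes at jittered multiples of the
#' programmed cycle length, optionally adds a secondary event train and
#' broadband white noise, and standardizes the result to zero mean and
#' unit variance.  Deterministic given `spec$seed`.
#'
#' @param spec an [nse_synthetic_spec][synthetic_spec()].
#' @return List with fields `signal` (normalized [nse_signal]) and `truth`
#'   (the generating spec, i.e. the ground-truth parameters).
#' @examples
#' rec <- generate_electrogram(synthetic_spec(df = 7, length = 4096, seed = 1))
#' rec$signal
#' @export
generate_electrogram <- function(spec) {
  stopifnot(inherits(spec, "nse_synthetic_spec"))
  validate_synthetic_spec(spec)
  if (!is.null(spec$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
  }
  len <- spec$length
  train <- numeric(len)
  if (!is.null(spec$df)) {
    train <- place_train(spec, spec$df, amp = 1, use_schedule = TRUE)
    if (!is.null(spec$secondary_df)) {
      # the rate schedule drives the primary train only; the secondary
      # periodicity keeps its own fixed rate
      train <- train + place_train(spec, spec$secondary_df, amp = spec$secondary_amp)
    }
    v <- mean((train - mean(train))^2)
    if (v > 0) train <- train / sqrt(v)
  }
  raw <- train + if (spec$noise_sd > 0) spec$noise_sd * rnorm(len) else 0
  sig <- normalize_signal(nse_signal(raw, spec$rate))
  list(signal = sig, truth = spec)
}

#' Generate a labeled two-class synthetic cohort
#'
#' Builds `n_records` synthetic electrograms split evenly between a
#' "persistent-like" class (more organized: low jitter and noise) and a
#' "paroxysmal-like" class (less organized: high jitter and noise),
#' mirroring the physiological contrast that electrical activity is less
#' organized in paroxysmal than in persistent atrial fibrillation.  Each
#' record's dominant frequency is drawn uniformly within `df_spread` Hz of
#' its class template (clamped to the 3-12 Hz band) and its seed is
#' derived from `seed`, so the cohort is fully reproducible.
#'
#' @param n_records total number of records, split evenly between classes
#'   (persistent-like gets the extra one when odd); must be >= 2.
#' @param persistent,paroxysmal class template
#'   [specs][synthetic_spec()].  Defaults: persistent-like df 6.5 Hz,
#'   jitter 0.03, noise 0.3; paroxysmal-like df 5.5 Hz, jitter 0.15,
#'   noise 1.0 (directionally consistent with the clinical contrast; the
#'   magnitudes are not calibrated to any cohort).
#' @param df_spread half-width (Hz) of the per-record uniform dominant
#'   frequency draw around the template value.
#' @param seed integer cohort seed.
#' @return List of class `nse_cohort`: one element per record with fields
#'   `signal`, `label` (`"persistent"` or `"paroxysmal"`) and `truth`.
#' @export
generate_cohort <- function(n_records,
                            persistent = synthetic_spec(df = 6.5, jitter_frac = 0.03,
                                                        noise_sd = 0.3),
                            paroxysmal = synthetic_spec(df = 5.5, jitter_frac = 0.15,
                                                        noise_sd = 1.0),
                            df_spread = 1.5, seed = 1) {
  if (!is.numeric(n_records) || n_records < 2) {
    stop("a cohort needs at least 2 records")
  }
  n_records <- as.integer(n_records)
  n_pers <- (n_records + 1L) %/% 2L
  labels <- rep(c("persistent", "paroxysmal"), c(n_pers, n_records - n_pers))
  templates <- list(persistent = persistent, paroxysmal = paroxysmal)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  records <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    tmpl <- templates[[labels[i]]]
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    tmpl$df <- min(12, max(3, tmpl$df + runif(1, -df_spread, df_spread)))
    tmpl$seed <- (seed + 104729L * i) %% .Machine$integer.max
    rec <- generate_electrogram(tmpl)
    rec$signal$channel <- i
    records[[i]] <- list(signal = rec$signal, label = labels[i], truth = rec$truth)
  }
  structure(records, class = "nse_cohort")
}

#' @export
print.nse_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  cat(sprintf("<nse_cohort> %d records (%d persistent-like, %d paroxysmal-like)\n",
              length(x), sum(labs == "persistent"), sum(labs == "paroxysmal")))
  invisible(x)
}
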