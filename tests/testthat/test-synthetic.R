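test_that("generation is deterministic given a seed and leaves the RNG alone", {
  spec <- synthetic_spec(977, 4096, df = 6, seed = 77)
  a <- generate_electrogram(spec)
  set.seed(1); before <- runif(1)
  b <- generate_electrogram(spec)
  set.seed(1); after <- runif(1)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(before, after)
  # different seeds give different records with the same ground truth
  c2 <- generate_electrogram(synthetic_spec(977, 4096, df = 6, seed = 78))
  expect_false(identical(a$signal$samples, c2$signal$samples))
})

test_that("every generated record satisfies the normalization invariant", {
  for (df in c(3.2, 7, 11.8)) {
    s <- generate_electrogram(synthetic_spec(977, 4096, df = df, seed = 5))$signal
    expect_true(s$normalized)
    expect_lt(abs(mean(s$samples)), 1e-9)
    expect_lt(abs(mean(s$samples^2) - 1), 1e-6)
  }
})

test_that("invalid specs are rejected with all offenders listed", {
  expect_error(synthetic_spec(df = 2.5), "3, 12")
  expect_error(synthetic_spec(df = 13), "3, 12")
  expect_error(synthetic_spec(jitter_frac = 0.7), "jitter")
  expect_error(synthetic_spec(df = 3, length = 100), "two cycles")
  expect_error(synthetic_spec(df = NULL, noise_sd = 0), "noise_sd > 0")
  err <- tryCatch(synthetic_spec(df = 2, jitter_frac = -1, noise_sd = -2),
                  error = conditionMessage)
  expect_match(err, "df")
  expect_match(err, "jitter")
  expect_match(err, "noise_sd")
  expect_error(synthetic_spec(df_schedule = data.frame(at = c(5, 2), df = c(4, 5))),
               "df_schedule")
})

test_that("jitter-free integer-period specs produce exactly periodic records", {
  w0 <- 200L; len <- 8192L
  s <- generate_electrogram(synthetic_spec(977, len, df = 977 / w0, jitter_frac = 0,
                                           amp_jitter = 0, noise_sd = 0, seed = 2))$signal
  expect_equal(s$samples[1:(len - w0)], s$samples[(w0 + 1):len])

  # with the window trimmed to a whole number of cycles, the tooth at the
  # programmed period carries the closed-form height sqrt(n)
  n <- len %/% w0
  win <- normalize_signal(nse_signal(s$samples[seq_len(n * w0)], 977))
  g <- build_period_grid(977, 3, 12)
  sp <- nse_spectrum_offline(win, g)
  expect_equal(sp$values[g$periods == w0], sqrt(n), tolerance = 1e-6)
  # the comb's tallest tooth sits at a harmonic of the programmed rate
  # (an exactly periodic signal is also periodic at every divisor period)
  pk <- dominant_peak(sp)
  m <- pk$DF / (977 / w0)
  expect_lt(abs(m - round(m)), 1e-6)
  expect_gte(sp$values[g$periods == w0], 0.9 * pk$DA)
})

test_that("noise-only records have a flat comb with no outstanding peak", {
  g <- build_period_grid(977, 3, 12)
  ratios <- sapply(1:5, function(r) {
    s <- generate_electrogram(synthetic_spec(977, 8192, df = NULL, noise_sd = 1,
                                             seed = 130 + r))$signal
    v <- nse_spectrum_offline(s, g)$values
    max(v) / mean(v)
  })
  expect_true(all(ratios < 3))
})

test_that("a secondary periodicity splits the comb into two peak families", {
  g <- build_period_grid(977, 3, 12)
  df1 <- 977 / 240; df2 <- 977 / 168    # grid-attainable rates ~4.07 and ~5.82 Hz
  s <- generate_electrogram(synthetic_spec(977, 8192, df = df1, jitter_frac = 0.01,
                                           noise_sd = 0.1, secondary_df = df2,
                                           secondary_amp = 0.8, seed = 17))$signal
  sp <- nse_spectrum_offline(s, g)
  f <- sp$grid$frequencies
  near <- function(f0) max(sp$values[abs(f - f0) < 0.15])
  baseline <- mean(sp$values)
  expect_gt(near(df1), 2 * baseline)
  expect_gt(near(df2), 2 * baseline)
})

test_that("a scheduled rate change moves the streaming dominant frequency", {
  g <- build_period_grid(977, 3, 12)
  sch <- data.frame(at = 8193L, df = 9)
  s <- generate_electrogram(synthetic_spec(977, 16384, df = 5, jitter_frac = 0.01,
                                           noise_sd = 0.2, df_schedule = sch,
                                           seed = 19))$signal
  cfg <- stream_config(g, N = 4096)
  set <- run_stream(s, cfg, emit_every = 4096)
  df_track <- spectral_params(set)$DF
  expect_lt(abs(df_track[2] - 5), 0.3)       # settled on the first rate
  expect_lt(abs(df_track[4] - 9), 0.5)       # settled on the new rate
})

test_that("cohorts are labeled, reproducible, and directionally separated", {
  co <- generate_cohort(4, seed = 9,
                        persistent = synthetic_spec(length = 4096, df = 6.5,
                                                    jitter_frac = 0.03, noise_sd = 0.3),
                        paroxysmal = synthetic_spec(length = 4096, df = 5.5,
                                                    jitter_frac = 0.15, noise_sd = 1.0))
  expect_length(co, 4)
  expect_equal(vapply(co, `[[`, character(1), "label"),
               c("persistent", "persistent", "paroxysmal", "paroxysmal"))
  co2 <- generate_cohort(4, seed = 9,
                         persistent = synthetic_spec(length = 4096, df = 6.5,
                                                     jitter_frac = 0.03, noise_sd = 0.3),
                         paroxysmal = synthetic_spec(length = 4096, df = 5.5,
                                                     jitter_frac = 0.15, noise_sd = 1.0))
  expect_identical(co[[1]]$signal$samples, co2[[1]]$signal$samples)
  expect_identical(co[[4]]$signal$samples, co2[[4]]$signal$samples)
  expect_error(generate_cohort(1), "at least 2")
  expect_error(generate_cohort(0), "at least 2")
})
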