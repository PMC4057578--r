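test_that("normalization centers, scales, and is idempotent", {
  s <- normalize_signal(nse_signal(c(1, 3), rate = 100))
  expect_equal(s$samples, c(-1, 1))
  expect_true(s$normalized)
  expect_equal(s$rate, 100)

  set.seed(11)
  x <- nse_signal(rnorm(500, mean = 3, sd = 4), rate = 977)
  nx <- normalize_signal(x)
  expect_lt(abs(mean(nx$samples)), 1e-12)
  expect_lt(abs(mean(nx$samples^2) - 1), 1e-12)
  # idempotence
  expect_equal(normalize_signal(nx)$samples, nx$samples, tolerance = 1e-12)
})

test_that("degenerate signals are rejected with the channel named", {
  expect_error(normalize_signal(nse_signal(c(5, 5, 5), 100)), "degenerate")
  expect_error(normalize_signal(nse_signal(rep(2, 10), 100, channel = "A3")), "A3")
  expect_error(nse_signal(numeric(0), 100), "at least one")
  expect_error(nse_signal(c(1, 2), rate = -1), "positive")
  # claiming normalization falsely is caught
  expect_error(nse_signal(c(1, 5, 9), 100, normalized = TRUE), "normalized")
})

test_that("period grid reproduces the study band and floor arithmetic", {
  g <- build_period_grid(977, 3, 12)
  expect_length(g$periods, 245)
  expect_equal(g$periods[1], 325L)
  expect_equal(g$periods[245], 81L)
  expect_true(all(diff(g$periods) == -1L))
  expect_true(all(diff(g$frequencies) > 0))
  expect_equal(g$frequencies, 977 / g$periods)

  g2 <- build_period_grid(1000, 3, 12)
  expect_equal(g2$frequencies[1], 1000 / 333)
  expect_equal(g2$frequencies[length(g2$frequencies)], 1000 / 83)

  g3 <- build_period_grid(100, 3, 12)
  expect_equal(range(g3$periods), c(8L, 33L))
  expect_length(g3$periods, 26)

  expect_error(build_period_grid(977, 3, 2), "band")
  # narrowest valid band collapses to a single period
  expect_length(build_period_grid(20, 9, 9.9)$periods, 1)
})

test_that("segment counts use the floor and reject short windows", {
  expect_identical(segment_count(8192, 81), 101L)
  expect_identical(segment_count(8192, 325), 25L)
  expect_identical(segment_count(8, 8), 1L)
  expect_error(segment_count(80, 81), "window too short")
})

test_that("ensemble mean averages aligned segments and matches a naive loop", {
  # tiling a fixed segment reproduces the segment exactly
  seg <- c(0.5, -1.5, 1, 0)
  x <- nse_signal(rep(seg, 6), 100)
  x$normalized <- TRUE   # bypass: tiling already has the structure under test
  em <- ensemble_mean(x, 4)
  expect_equal(em$values, seg)
  expect_equal(em$n, 6L)

  a <- 1.3
  x2 <- nse_signal(c(a, -a, a, -a), 100, normalized = FALSE)
  x2$normalized <- TRUE
  em2 <- ensemble_mean(x2, 2)
  expect_equal(em2$values, c(a, -a))
  expect_equal(em2$n, 2L)

  # independent double-loop oracle on random signals, remainder discarded
  set.seed(21)
  for (rep in 1:5) {
    x3 <- make_white_signal(173)
    w <- sample(2:60, 1)
    em3 <- ensemble_mean(x3, w)
    n <- floor(173 / w)
    ref <- numeric(w)
    for (j in 1:w) for (i in 0:(n - 1)) ref[j] <- ref[j] + x3$samples[i * w + j] / n
    expect_equal(em3$values, ref, tolerance = 1e-12)
  }
  expect_error(ensemble_mean(nse_signal(1:10, 100), 3), "normalize")
})

test_that("offline spectrum matches the naive transcription within 1e-9", {
  set.seed(31)
  for (N in c(700, 1500)) {
    x <- make_white_signal(N)
    g <- build_period_grid(200, 3, 12)
    s <- nse_spectrum_offline(x, g)
    ref <- naive_nse_spectrum(x$samples, g$periods)
    expect_lt(max(abs(s$values - ref) / pmax(ref, 1e-12)), 1e-9)
  }
})

test_that("offline spectrum: zero signal, periodic peak, white-noise baseline", {
  g <- build_period_grid(977, 3, 12)
  z <- nse_signal(numeric(600), 977)
  z$normalized <- TRUE   # bypass: the zero signal cannot be normalized
  expect_true(all(nse_spectrum_offline(z, g)$values == 0))

  # exactly periodic unit-variance signal with N a multiple of w0: S = sqrt(n)
  w0 <- 256L; N <- 8192L; n <- N / w0
  x <- generate_electrogram(synthetic_spec(977, N, df = 977 / w0, jitter_frac = 0,
                                           amp_jitter = 0, noise_sd = 0, seed = 5))
  s <- nse_spectrum_offline(x$signal, g)
  expect_equal(s$values[g$periods == w0], sqrt(n), tolerance = 1e-6)
  expect_equal(s$values[g$periods == w0], sqrt(N / w0), tolerance = 1e-6)

  # flat baseline near 1 for white noise (sqrt(n)-scaling rationale)
  set.seed(41)
  gm <- replicate(20, mean(nse_spectrum_offline(make_white_signal(8192), g)$values))
  expect_true(all(gm > 0.8 & gm < 1.2))
})

test_that("halved path agrees with the direct path exactly where promised", {
  g <- build_period_grid(977, 3, 12)
  set.seed(51)
  x <- make_white_signal(8192)
  sd_ <- nse_spectrum_offline(x, g)
  sh <- nse_spectrum_offline_halved(x, g)
  N <- 8192
  used <- vapply(g$periods, halved_segments_used, numeric(1), N = N, periods = g$periods)
  exact <- used == floor(N / g$periods)
  expect_gt(sum(exact), 0)
  expect_equal(sh$values[exact], sd_$values[exact], tolerance = 1e-12)

  # where segments are dropped, the halved value equals the direct
  # computation restricted to the segments actually used
  for (i in which(!exact)[c(1, sum(!exact))]) {
    w <- g$periods[i]
    xr <- nse_signal(x$samples[seq_len(used[i] * w)], 977)
    xr$normalized <- TRUE
    ref <- sqrt(sum(segment_sums_for_test(xr$samples, w)^2)) / sqrt(N)
    expect_equal(sh$values[i], ref, tolerance = 1e-12)
  }

  # N = 400, w = 100: n = 4 = 2 * 2, exact agreement case from first principles
  x4 <- make_white_signal(400, rate = 1000, seed = 6)
  g4 <- build_period_grid(1000, 4, 11)
  s4d <- nse_spectrum_offline(x4, g4)
  s4h <- nse_spectrum_offline_halved(x4, g4)
  i100 <- which(g4$periods == 100L)
  expect_equal(s4h$values[i100], s4d$values[i100], tolerance = 1e-12)
})
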