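make_stack_with_trace <- function(H = 6, W = 6, T = 800, fs = 40, seed = 1) {
  set.seed(seed)
  tr <- smooth_noise(T, seed = seed)
  fr <- array(rnorm(H * W * T, sd = 0.5), c(H, W, T))
  list(frames = fr, trace = tr, fs = fs)
}

test_that("correlation map is exact for copied and negated pixels", {
  s <- make_stack_with_trace()
  s$frames[2, 3, ] <- s$trace
  s$frames[4, 5, ] <- -s$trace
  st <- widefield_stack(s$frames, s$fs)
  cm <- correlation_map(st, fp_trace(s$trace, s$fs))
  expect_equal(cm$values[2, 3], 1, tolerance = 1e-10)
  expect_equal(cm$values[4, 5], -1, tolerance = 1e-10)
  expect_true(all(abs(cm$values[cm$mask]) <= 1))
})

test_that("correlation map matches the closed-form expectation and oracle", {
  T <- 4000
  fs <- 40
  set.seed(13)
  trace <- rnorm(T, sd = 2)
  a <- 0.8
  sn <- 1.5
  fr <- array(rnorm(4 * 4 * T, sd = sn), c(4, 4, T))
  fr[1, 1, ] <- a * trace + rnorm(T, sd = sn)
  st <- widefield_stack(fr, fs)
  cm <- correlation_map(st, fp_trace(trace, fs))
  expected <- a * 2 / sqrt(a^2 * 4 + sn^2)
  se <- (1 - expected^2) / sqrt(T)
  expect_lt(abs(cm$values[1, 1] - expected), 3 * se)
  expect_equal(cm$values[1, 1], oracle_pearson(fr[1, 1, ], trace),
               tolerance = 1e-10)
})

test_that("partial correlation handles degenerate and reduction cases", {
  T <- 600
  fs <- 40
  set.seed(14)
  g <- smooth_noise(T, seed = 3)
  trace <- rnorm(T)
  fr <- array(rnorm(2 * 2 * T), c(2, 2, T))
  fr[1, 1, ] <- g # pixel identical to the global signal
  st <- widefield_stack(fr, fs)
  pm <- partial_correlation_map(st, fp_trace(trace, fs), fp_trace(g, fs))
  expect_equal(pm$values[1, 1], 0)
  expect_true(pm$degenerate[1, 1])
  expect_error(
    partial_correlation_map(st, fp_trace(trace, fs),
                            fp_trace(rep(1, T), fs)),
    "constant")
})

test_that("partial correlation equals the residual-regression construction", {
  set.seed(15)
  T <- 500
  worst <- 0
  for (i in 1:100) {
    x <- rnorm(T)
    z <- rnorm(T)
    y <- 0.3 * x + 0.4 * z + rnorm(T)
    x <- x + 0.5 * z
    fr <- array(rnorm(1 * 2 * T), c(1, 2, T))
    fr[1, 1, ] <- x
    st <- widefield_stack(fr, fs = 40)
    pm <- partial_correlation_map(st, fp_trace(y, 40), fp_trace(z, 40))
    worst <- max(worst, abs(pm$values[1, 1] - oracle_partial_cor(x, y, z)))
  }
  expect_lt(worst, 1e-10)
})

test_that("partial correlation reduces to full when the control is unrelated", {
  set.seed(16)
  T <- 20000
  x <- rnorm(T)
  y <- 0.5 * x + rnorm(T)
  z <- rnorm(T)
  fr <- array(0, c(1, 2, T))
  fr[1, 1, ] <- x
  fr[1, 2, ] <- rnorm(T)
  st <- widefield_stack(fr, fs = 40)
  pm <- partial_correlation_map(st, fp_trace(y, 40), fp_trace(z, 40))
  cm <- correlation_map(st, fp_trace(y, 40))
  # with finite samples the reduction holds up to the sampling error of the
  # nuisance correlations (~1/sqrt(T) each)
  expect_lt(abs(pm$values[1, 1] - cm$values[1, 1]), 3 / sqrt(T))
  # exact algebraic reduction when the nuisance correlations are zero:
  # verified through the closed form directly
  r_xy <- 0.62
  expect_equal((r_xy - 0 * 0) / sqrt((1 - 0) * (1 - 0)), r_xy)
})

test_that("xcorr_lag follows the stated sign convention", {
  x <- smooth_noise(2000, seed = 17)
  a <- fp_trace(x, 40)
  expect_equal(xcorr_lag(a, a, 1)$lag, 0)
  expect_equal(xcorr_lag(a, a, 1)$peak_r, 1, tolerance = 1e-12)
  # b = a delayed by 12 samples at 40 Hz: a leads, lag = -0.300 s
  b <- fp_trace(c(rep(0, 12), x[1:1988]), 40)
  xc <- xcorr_lag(a, b, 1)
  expect_equal(xc$lag, -0.3)
  expect_gt(xc$peak_r, 0.99)
})

test_that("xcorr_lag equals the exhaustive-lag oracle on a noisy pair", {
  set.seed(18)
  x <- smooth_noise(1500, seed = 18)
  y <- c(rep(0, 7), x[1:1493]) + rnorm(1500, sd = 0.1)
  a <- fp_trace(x, 40)
  b <- fp_trace(y, 40)
  xc <- xcorr_lag(a, b, 0.5)
  oc <- oracle_xcorr(x, y, 40, 0.5)
  expect_equal(xc$lag, oc$lag)
  expect_equal(xc$peak_r, oc$peak_r, tolerance = 1e-12)
})

test_that("xcorr_lag is antisymmetric and frame-quantized", {
  set.seed(19)
  for (i in 1:5) {
    x <- smooth_noise(1200, seed = 100 + i)
    d <- sample(1:10, 1)
    y <- c(rep(0, d), x[1:(1200 - d)]) + rnorm(1200, sd = 0.05)
    a <- fp_trace(x, 40)
    b <- fp_trace(y, 40)
    f <- xcorr_lag(a, b, 0.5)
    r <- xcorr_lag(b, a, 0.5)
    expect_lte(abs(f$lag + r$lag), 1 / 40 + 1e-12)
    expect_equal(f$lag * 40, round(f$lag * 40), tolerance = 1e-9)
  }
})

test_that("lag map reads planted regional delays exactly", {
  T <- 2000
  fs <- 40
  x <- smooth_noise(T + 40, seed = 20)
  trace <- x[17:(16 + T)]
  fr <- array(rnorm(8 * 8 * T, sd = 1), c(8, 8, T))
  # region A: trace advanced by 0.3 s (12 frames); cortex leads
  for (i in 1:3) for (j in 1:8) fr[i, j, ] <- x[(17 + 12):(16 + T + 12)]
  # region B: advanced by 0.4 s (16 frames)
  for (i in 6:8) for (j in 1:8) fr[i, j, ] <- x[(17 + 16):(16 + T + 16)]
  st <- widefield_stack(fr, fs)
  lm <- lag_map(st, fp_trace(trace, fs), max_lag = 1, r_threshold = 0.5)
  expect_equal(unique(as.vector(lm$lags[1:3, ])), -0.3)
  expect_equal(unique(as.vector(lm$lags[6:8, ])), -0.4)
  expect_true(all(lm$valid[1:3, ]))
  expect_true(all(lm$valid[6:8, ]))
  # pure-noise middle rows: no pixel reaches the 0.5 threshold
  expect_false(any(lm$valid[4:5, ]))
})

test_that("lag map reduces to xcorr_lag for a single-pixel mask", {
  T <- 1200
  set.seed(21)
  x <- smooth_noise(T, seed = 21)
  y <- c(rep(0, 5), x[1:(T - 5)]) + rnorm(T, sd = 0.2)
  fr <- array(rnorm(3 * 3 * T), c(3, 3, T))
  fr[2, 2, ] <- y
  mask <- matrix(FALSE, 3, 3)
  mask[2, 2] <- TRUE
  st <- widefield_stack(fr, fs = 40, mask = mask)
  lm <- lag_map(st, fp_trace(x, 40), max_lag = 0.5, r_threshold = 0.5)
  xc <- xcorr_lag(fp_trace(y, 40), fp_trace(x, 40), 0.5)
  expect_equal(lm$lags[2, 2], xc$lag)
  expect_equal(lm$peak_r[2, 2], xc$peak_r, tolerance = 1e-10)
})

test_that("full-map footprint separates coupled from uncoupled cortex", {
  # sustained (non-travelling) coupled motif: its pixels are active for the
  # full motif duration, which is what a correlation map selects for
  cfg <- scene_config(height = 24, width = 24, duration_s = 240,
                      motifs = list(motif_spec("alm_visual",
                                               rate_hz = 0.3,
                                               l_frames = 121)),
                      couplings = list(coupling_spec(delay_ms = 300)),
                      noise_sd_widefield = 0.25, noise_sd_photometry = 0.02,
                      seed = 22)
  ses <- generate_spontaneous_session(cfg)
  st <- preprocess_stack(ses$stack)
  tr <- preprocess_photometry(ses$photometry, ses$stack$fs,
                              t_out = frame_times(ses$stack))
  cm <- correlation_map(st, tr)
  fp <- apply(ses$truth$motif_templates[[1]], c(1, 2), max) > 0
  inside <- cm$values[fp & cm$mask]
  outside <- cm$values[!fp & cm$mask]
  expect_gt(mean(inside) - mean(outside), 0.3)
})
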