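planted_instance <- function(P = 50, T = 600, L = 10,
                             events = c(30, 90, 200, 340, 480, 550)) {
  tpl <- matrix(0, P, L)
  for (l in seq_len(L)) tpl[((l - 1) * 5 + 1):(l * 5), l] <- 1
  X <- matrix(0, P, T)
  for (t0 in events) X[, t0:(t0 + L - 1)] <- X[, t0:(t0 + L - 1)] + tpl
  list(X = X, tpl = tpl, events = events)
}

test_that("seq-NMF recovers a planted template and its event train", {
  pi_ <- planted_instance()
  fit <- seqnmf_fit(pi_$X, K = 1, L = 10, lambda = 0, n_iter = 100, seed = 3)
  R <- reconstruct(fit)
  expect_lt(sqrt(sum((pi_$X - R)^2) / sum(pi_$X^2)), 1e-2)
  # recovered template matches the planted one frame-by-frame (up to a
  # frame shift <= 2, but onset alignment should land it exactly here)
  shifts <- -2:2
  cors <- sapply(shifts, function(s) {
    w <- sapply(1:10, function(l) {
      ls <- l + s
      if (ls < 1 || ls > 10) rep(0, 50) else fit$W[, 1, ls]
    })
    suppressWarnings(cor(as.vector(w), as.vector(pi_$tpl)))
  })
  expect_gt(max(cors, na.rm = TRUE), 0.95)
  ev <- which(fit$H[1, ] > 0.5 * max(fit$H[1, ]))
  expect_equal(ev, pi_$events)
})

test_that("objective is non-increasing at lambda = 0", {
  pi_ <- planted_instance()
  set.seed(23)
  Xn <- pi_$X + matrix(abs(rnorm(length(pi_$X), sd = 0.1)), nrow(pi_$X))
  fit <- seqnmf_fit(Xn, K = 2, L = 10, lambda = 0, n_iter = 80, seed = 4,
                    recenter = FALSE, align = "none")
  o <- fit$objective
  expect_true(all(diff(o) <= 1e-9 * pmax(abs(o[-length(o)]), 1)))
})

test_that("zero input gives a zero reconstruction and objective", {
  fit <- seqnmf_fit(matrix(0, 10, 100), K = 1, L = 5, n_iter = 2, seed = 1)
  expect_equal(reconstruct(fit), matrix(0, 10, 100))
  expect_equal(fit$objective[length(fit$objective)], 0)
})

test_that("seq-NMF validates its inputs", {
  X <- matrix(1, 10, 50)
  expect_error(seqnmf_fit(X - 2, K = 1, L = 5), "nonnegative")
  expect_error(seqnmf_fit(X, K = 20, L = 5), "exceeds")
})

test_that("reconstruct matches the direct convolution oracle", {
  set.seed(24)
  W <- array(runif(12 * 2 * 3), c(12, 2, 3))
  H <- matrix(runif(2 * 30), 2, 30)
  ms <- structure(list(W = W, H = H, K = 2L, L = 3L), class = "motif_set")
  expect_equal(reconstruct(ms), oracle_reconstruct(W, H), tolerance = 1e-10)
  # single impulse places the template at the event
  H0 <- matrix(0, 2, 30)
  H0[1, 7] <- 1
  ms$H <- H0
  R <- reconstruct(ms)
  expect_equal(R[, 7:9], matrix(W[, 1, ], 12, 3), tolerance = 1e-12)
  expect_equal(R[, c(1:6, 10:30)], matrix(0, 12, 27))
  ms$H <- matrix(0, 2, 30)
  expect_equal(reconstruct(ms), matrix(0, 12, 30))
})

test_that("fits are scale-covariant and seed-deterministic", {
  pi_ <- planted_instance()
  f1 <- seqnmf_fit(pi_$X, K = 1, L = 10, n_iter = 60, seed = 5)
  f2 <- seqnmf_fit(3 * pi_$X, K = 1, L = 10, n_iter = 60, seed = 5)
  # normalized templates agree; loadings absorb the scale
  expect_equal(f2$W, f1$W, tolerance = 1e-6)
  expect_equal(f2$H, 3 * f1$H, tolerance = 1e-4)
  f3 <- seqnmf_fit(pi_$X, K = 1, L = 10, n_iter = 60, seed = 5)
  expect_identical(f1$W, f3$W)
  expect_identical(f1$H, f3$H)
})

test_that("motif recovery holds with 2 planted motifs at 20% noise", {
  # amplitudes chosen so the two motif classes carry comparable energy:
  # the sustained pattern's decaying envelope holds less energy per event
  # at equal peak amplitude
  cfg <- scene_config(height = 24, width = 24, duration_s = 150,
                      motifs = list(motif_spec("travelling_blob",
                                               rate_hz = 0.2, amplitude = 5),
                                    motif_spec("alm_visual",
                                               rate_hz = 0.2, amplitude = 8)),
                      couplings = list(coupling_spec(delay_ms = 300)),
                      noise_sd_widefield = 1, noise_sd_photometry = 0.02,
                      drift_amplitude = 0, seed = 25)
  ses <- generate_spontaneous_session(cfg)
  st <- stack_dff(ses$stack)
  X <- stack_matrix(st, masked_only = TRUE)
  X[X < 0] <- 0
  fit <- seqnmf_fit(X, K = 2, L = 20, n_iter = 100, seed = 6)
  truth_proj <- lapply(ses$truth$motif_templates, function(tp)
    apply(tp, c(1, 2), max)[ses$stack$mask])
  rec_proj <- lapply(1:2, function(k) apply(fit$W[, k, ], 1, max))
  cors <- outer(1:2, 1:2, Vectorize(function(i, j)
    cor(truth_proj[[i]], rec_proj[[j]])))
  best <- max(min(diag(cors)), min(cors[1, 2], cors[2, 1]))
  expect_gt(best, 0.8)
})

test_that("motif-photometry cross-correlation recovers a planted delay", {
  set.seed(26)
  T <- 4000
  H <- matrix(0, 2, T)
  H[1, sample(1:(T - 50), 25)] <- 1
  H[2, sample(1:(T - 50), 25)] <- 1
  ms <- structure(list(W = array(1, c(5, 2, 3)), H = H, K = 2L, L = 3L),
                  class = "motif_set")
  # trace equals loading row 1 itself: (0, 1)
  tr <- fp_trace(H[1, ], 40)
  mx <- motif_photometry_xcorr(ms, tr, 1)
  expect_equal(mx$lag_s[mx$motif == 1], 0)
  expect_equal(mx$peak_r[mx$motif == 1], 1, tolerance = 1e-10)
  # trace coupled to motif 1 with a 700 ms delay; motif 2 uncoupled
  d <- 28
  kern <- exp(-(0:80) / 40)
  cp <- as.numeric(stats::filter(c(rep(0, d), H[1, 1:(T - d)]),
                                 kern, sides = 1, method = "convolution"))
  cp[is.na(cp)] <- 0
  cp <- cp + rnorm(T, sd = 0.01)
  mx <- motif_photometry_xcorr(ms, fp_trace(cp, 40), 2)
  expect_equal(mx$motif[1], 1)
  expect_lte(abs(mx$lag_s[1] - (-0.7)), 1 / 40 + 1e-12)
  expect_gt(mx$peak_r[1], mx$peak_r[2])
  # all-zero trace is flagged
  expect_warning(mz <- motif_photometry_xcorr(ms, fp_trace(rep(0, T), 40), 1),
                 "degenerate")
  expect_true(all(mz$degenerate))
})

test_that("motif-map similarity separates map-like from disjoint motifs", {
  mask <- matrix(TRUE, 8, 8)
  footA <- matrix(0, 8, 8)
  footA[2:4, 2:6] <- 1
  footB <- matrix(0, 8, 8)
  footB[6:8, 2:6] <- 1
  W <- array(0, c(64, 2, 2))
  W[, 1, 1] <- as.vector(footA)
  W[, 2, 1] <- as.vector(footB)
  ms <- structure(list(W = W, H = matrix(1, 2, 10), K = 2L, L = 2L),
                  class = "motif_set")
  cmap <- structure(list(values = footA, kind = "full", mask = mask),
                    class = "correlation_map")
  sim <- motif_map_similarity(ms, cmap)
  expect_equal(sim$similarity[1], 1, tolerance = 1e-12)
  expect_lte(sim$similarity[2], 0)
  expect_equal(sim$similarity[2],
               oracle_pearson(as.vector(footB), as.vector(footA)),
               tolerance = 1e-12)
})

test_that("coupled motifs score higher map similarity than uncoupled ones", {
  cfg <- scene_config(height = 24, width = 24, duration_s = 120,
                      motifs = list(motif_spec("travelling_blob",
                                               rate_hz = 0.25),
                                    motif_spec("alm_visual", rate_hz = 0.25)),
                      couplings = list(coupling_spec(motif = 1,
                                                     delay_ms = 300)),
                      noise_sd_widefield = 0.5, seed = 27)
  ses <- generate_spontaneous_session(cfg)
  st <- preprocess_stack(ses$stack)
  tr <- preprocess_photometry(ses$photometry, 40,
                              t_out = frame_times(ses$stack))
  cm <- correlation_map(st, tr)
  # build a motif_set from the planted truth and score it
  mask <- ses$stack$mask
  K <- 2
  W <- array(0, c(sum(mask), K, 20))
  for (k in 1:K)
    for (l in 1:20)
      W[, k, l] <- ses$truth$motif_templates[[k]][, , l][mask]
  ms <- structure(list(W = W, H = ses$truth$loadings, K = 2L, L = 20L),
                  class = "motif_set")
  sim <- motif_map_similarity(ms, cm)
  expect_gt(sim$similarity[1], sim$similarity[2])
})

test_that("empty motifs are identified by loading energy", {
  H <- matrix(0, 2, 100)
  H[1, c(10, 50)] <- 1
  ms <- structure(list(W = array(1, c(4, 2, 2)), H = H, K = 2L, L = 2L),
                  class = "motif_set")
  expect_equal(empty_motifs(ms), c(FALSE, TRUE))
})
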