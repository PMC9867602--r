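test_that("travelling-blob template propagates anterior to posterior", {
  cfg <- scene_config(height = 32, width = 32, duration_s = 60,
                      motifs = list(motif_spec("travelling_blob",
                                               l_frames = 40, amplitude = 3)))
  tpl <- generate_motif_templates(cfg)[[1]]
  expect_true(all(tpl >= 0))
  expect_equal(max(tpl), 3)
  centroids <- sapply(1:40, function(l) {
    fr <- tpl[, , l]
    sum(row(fr) * fr) / sum(fr)
  })
  expect_true(all(diff(centroids) > 0))
})

test_that("template footprints are disjoint between the two classes", {
  cfg <- scene_config(height = 32, width = 32, duration_s = 60,
                      motifs = list(motif_spec("travelling_blob"),
                                    motif_spec("alm_visual")))
  tpls <- generate_motif_templates(cfg)
  p1 <- apply(tpls[[1]], c(1, 2), max)
  p2 <- apply(tpls[[2]], c(1, 2), max)
  expect_equal(sum(p1 * p2), 0)
  expect_gt(sum(p2), 0)
})

test_that("unknown template ids raise a parameter error", {
  cfg <- scene_config(motifs = list(motif_spec("travelling_blob")))
  cfg$motifs[[1]]$template <- "nope"
  expect_error(generate_motif_templates(cfg), "unknown template")
})

test_that("a structureless configuration yields constant outputs", {
  cfg <- scene_config(height = 8, width = 8, duration_s = 30,
                      motifs = list(), couplings = list(),
                      drift_amplitude = 0, noise_sd_widefield = 0,
                      noise_sd_photometry = 0, seed = 1)
  ses <- generate_spontaneous_session(cfg)
  expect_equal(ses$stack$frames, array(100, c(8, 8, 1200)))
  expect_equal(ses$photometry$f465$samples, rep(100, 30000))
  expect_equal(ses$photometry$f405$samples, rep(100, 30000))
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_scene(seed = 31)
  a <- generate_spontaneous_session(cfg)
  b <- generate_spontaneous_session(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$photometry$f465$samples, b$photometry$f465$samples)
  expect_identical(a$photometry$f405$samples, b$photometry$f405$samples)
  expect_identical(a$truth$loadings, b$truth$loadings)
})

test_that("a 300 ms coupling shows up at -300 ms in the brute-force xcorr", {
  # single-frame motif so the spatial-mean trace is the event train itself
  cfg <- scene_config(height = 16, width = 16, duration_s = 120,
                      motifs = list(motif_spec("travelling_blob",
                                               l_frames = 1, rate_hz = 0.3)),
                      couplings = list(coupling_spec(delay_ms = 300)),
                      drift_amplitude = 0, noise_sd_widefield = 0,
                      noise_sd_photometry = 0, seed = 32)
  ses <- generate_spontaneous_session(cfg)
  g <- global_signal(ses$stack)$samples
  ph <- resample_trace(ses$photometry$f465, 40,
                       t_out = frame_times(ses$stack))$samples
  oc <- oracle_xcorr(g, ph, 40, 1)
  expect_equal(oc$lag, -0.3)
})

test_that("stack deviation from baseline is linear in motif amplitude", {
  base <- scene_config(height = 16, width = 16, duration_s = 60,
                       motifs = list(motif_spec(amplitude = 2,
                                                rate_hz = 0.2)),
                       couplings = list(),
                       drift_amplitude = 0, noise_sd_widefield = 0,
                       noise_sd_photometry = 0, seed = 33)
  dbl <- base
  dbl$motifs[[1]]$amplitude <- 4
  s1 <- generate_spontaneous_session(base)
  s2 <- generate_spontaneous_session(dbl)
  expect_equal(s2$stack$frames - 100, 2 * (s1$stack$frames - 100),
               tolerance = 1e-12)
})

test_that("the isosbestic channel is uncorrelated with motif loadings", {
  cfg <- scene_config(height = 8, width = 8, duration_s = 600,
                      motifs = list(motif_spec(rate_hz = 0.3)),
                      couplings = list(coupling_spec()),
                      noise_sd_photometry = 0.5, seed = 34)
  ses <- generate_spontaneous_session(cfg)
  f405 <- resample_trace(ses$photometry$f405, 40,
                         t_out = frame_times(ses$stack))$samples
  load_sm <- as.numeric(stats::filter(ses$truth$loadings[1, ],
                                      rep(1, 40), sides = 1))
  load_sm[is.na(load_sm)] <- 0
  expect_lt(abs(cor(f405, load_sm)), 0.1)
})

test_that("evoked habituation follows the configured geometric decay", {
  mk <- function(decay) {
    scene_config(height = 12, width = 12, duration_s = 420,
                 motifs = list(), couplings = list(),
                 drift_amplitude = 0, noise_sd_widefield = 0,
                 noise_sd_photometry = 0,
                 stimulus = stimulus_spec(n_stimuli = 40, isi_s = 10,
                                          onset_s = 5,
                                          habituation_decay = decay),
                 seed = 35)
  }
  ses <- generate_evoked_session(mk(1))
  g <- global_signal(ses$stack)
  ep <- extract_epochs(g, ses$truth$stimulus_times_s, 1, 2)
  ev <- trial_average_first_last(ep, 10)
  expect_equal(ev$amplitude_first, ev$amplitude_last, tolerance = 1e-10)

  ses <- generate_evoked_session(mk(0.9))
  ep <- extract_epochs(global_signal(ses$stack),
                       ses$truth$stimulus_times_s, 1, 2)
  ev <- trial_average_first_last(ep, 10)
  expected <- sum(0.9^(30:39)) / sum(0.9^(0:9))
  expect_equal(ev$habituation_ratio, expected, tolerance = 1e-9)
  expect_equal(ses$truth$habituation_factors, 0.9^(0:39))
})

test_that("a zero-amplitude artifact leaves the session untouched", {
  mk <- function(art) {
    scene_config(height = 10, width = 10, duration_s = 120,
                 motifs = list(), couplings = list(),
                 stimulus = stimulus_spec(n_stimuli = 10, isi_s = 10,
                                          onset_s = 5,
                                          artifact_amplitude = art),
                 seed = 36)
  }
  a <- generate_evoked_session(mk(0))
  b <- generate_evoked_session(mk(2))
  expect_identical(a$stack$frames[, , 1:100], b$stack$frames[, , 1:100])
  f <- round(5 * 40) + 1
  expect_equal(b$stack$frames[, , f] - a$stack$frames[, , f],
               matrix(2, 10, 10), tolerance = 1e-12)
})

test_that("invalid schedules and durations raise parameter errors", {
  expect_error(
    generate_evoked_session(
      scene_config(duration_s = 60,
                   stimulus = stimulus_spec(n_stimuli = 40, isi_s = 10))),
    "exceeds")
  expect_error(
    generate_evoked_session(scene_config(duration_s = 60)),
    "no stimulus")
  cfg <- scene_config(duration_s = 0.5,
                      motifs = list(motif_spec(l_frames = 40)))
  expect_error(generate_spontaneous_session(cfg), "too short")
  expect_error(scene_config(couplings = list(coupling_spec(motif = 5))),
               "unknown motif")
  expect_error(scene_config(fs_widefield = 100, fs_photometry = 40))
})
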