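# Synthetic corticostriatal sessions with planted ground truth.
#
# The generator emulates the recording regime of a combined mesoscale
# widefield / striatal fiber photometry experiment: 40 Hz cortical movies
# built from repeating spatiotemporal motifs (anterior-to-posterior
# travelling "butterfly" pattern and a spatially disjoint ALM+visual
# pattern), a ~1 kHz two-channel photometry trace whose 465 nm channel is
# coupled to chosen motifs with a fixed delay, slow drift shared with the
# 405 nm isosbestic channel, Gaussian noise, and an optional stimulus block
# (40 stimuli at 10 s ISI with geometric per-trial habituation).

#' Synthetic session configuration
#'
#' Full parameterization of a synthetic corticostriatal session. Defaults
#' follow the recording regime the pipeline targets: 40 Hz widefield
#' frames, ~1 kHz photometry, 1-s (40-frame) motifs, and a 40-stimulus
#' 10-s-ISI schedule for evoked sessions.
#'
#' @param height,width Frame size in pixels.
#' @param duration_s Session duration in seconds.
#' @param fs_widefield Widefield frame rate in Hz (default 40).
#' @param fs_photometry Photometry sampling rate in Hz (default 1000); must
#'   be >= `fs_widefield`.
#' @param motifs List of motif specifications, each a list with `template`
#'   (`"travelling_blob"` or `"alm_visual"`), `l_frames` (motif length,
#'   default 40), `rate_hz` (motif event rate, default 0.2), and
#'   `amplitude` (peak fluorescence units, default 5).
#' @param couplings List of photometry couplings, each a list with `motif`
#'   (index into `motifs`), `weight` (transient amplitude in fluorescence
#'   units, default 5) and `delay_ms` (striatal delay; positive means the
#'   cortex leads).
#' @param baseline Baseline fluorescence level (default 100).
#' @param drift_amplitude Drift amplitude as a fraction of baseline
#'   (default 0.02); the drift is a slow sinusoid shared between the 465
#'   and 405 channels so the isosbestic fit has real structure to remove.
#' @param drift_timescale_s Drift period in seconds (default 60).
#' @param noise_sd_widefield,noise_sd_photometry Gaussian noise SDs in
#'   fluorescence units.
#' @param kernel_tau_s Photometry transient decay time constant in seconds
#'   (default 1, approximating slow GCaMP indicator kinetics).
#' @param kernel_rise_s Photometry transient rise time constant in seconds
#'   (default 0.05). The transient kernel's peak is aligned to the coupling
#'   delay, so the planted delay is exactly what a cross-correlation peak
#'   measures.
#' @param uncoupled_photometry_sd SD of an optional smooth striatal
#'   component not explained by any cortical motif (default 0), standing in
#'   for, e.g., thalamic drive.
#' @param stimulus Optional stimulus block from [stimulus_spec()].
#' @param seed Integer seed; all randomness flows from per-component
#'   sub-streams derived from it in fixed order.
#' @return A `scene_config` list.
#' @export
scene_config <- function(height = 32, width = 32, duration_s = 1200,
                         fs_widefield = 40, fs_photometry = 1000,
                         motifs = list(motif_spec()),
                         couplings = list(coupling_spec()),
                         baseline = 100, drift_amplitude = 0.02,
                         drift_timescale_s = 60,
                         noise_sd_widefield = 0.5,
                         noise_sd_photometry = 0.05,
                         kernel_tau_s = 1, kernel_rise_s = 0.05,
                         uncoupled_photometry_sd = 0,
                         stimulus = NULL, seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              duration_s = duration_s, fs_widefield = fs_widefield,
              fs_photometry = fs_photometry, motifs = motifs,
              couplings = couplings, baseline = baseline,
              drift_amplitude = drift_amplitude,
              drift_timescale_s = drift_timescale_s,
              noise_sd_widefield = noise_sd_widefield,
              noise_sd_photometry = noise_sd_photometry,
              kernel_tau_s = kernel_tau_s, kernel_rise_s = kernel_rise_s,
              uncoupled_photometry_sd = uncoupled_photometry_sd,
              stimulus = stimulus, seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

#' @rdname scene_config
#' @param template Spatial template id.
#' @param l_frames Motif length in frames (>= 1).
#' @param rate_hz Motif event rate in events per second.
#' @param amplitude Peak motif amplitude in fluorescence units.
#' @export
motif_spec <- function(template = "travelling_blob", l_frames = 40,
                       rate_hz = 0.2, amplitude = 5) {
  list(template = template, l_frames = as.integer(l_frames),
       rate_hz = rate_hz, amplitude = amplitude)
}

#' @rdname scene_config
#' @param motif Index of the coupled motif.
#' @param weight Photometry transient amplitude (fluorescence units).
#' @param delay_ms Corticostriatal delay in milliseconds.
#' @param mode Delay convention. `"peak"` (default) places the transient
#'   kernel's peak at `delay_ms` after the loading event, so a
#'   cross-correlation between the (impulse-like) motif loading and the
#'   photometry trace peaks at exactly `-delay_ms`. `"attack"` places the
#'   kernel's onset at `delay_ms` after the event; combined with a motif
#'   whose temporal envelope is the same indicator kernel (the sustained
#'   template), the photometry is then a pure time shift of the cortical
#'   pixel signals and the pixel-level lag map reads `-delay_ms`.
#' @export
coupling_spec <- function(motif = 1L, weight = 5, delay_ms = 300,
                          mode = c("peak", "attack")) {
  mode <- match.arg(mode)
  list(motif = as.integer(motif), weight = weight, delay_ms = delay_ms,
       mode = mode)
}

#' @rdname scene_config
#' @param n_stimuli Number of stimuli (default 40).
#' @param isi_s Inter-stimulus interval in seconds (default 10).
#' @param onset_s Time of the first stimulus (default 10).
#' @param amplitude Evoked-response peak amplitude (fluorescence units).
#' @param habituation_decay Per-trial geometric amplitude factor; trial i is
#'   scaled by `habituation_decay^(i-1)` (default 0.9, a moderately
#'   habituating response).
#' @param artifact_amplitude One-frame stimulus artifact amplitude added to
#'   every pixel at the stimulus frame (default 0).
#' @param coupling_weight Photometry transient amplitude per stimulus.
#' @param coupling_delay_ms Photometry delay for evoked transients.
#' @export
stimulus_spec <- function(n_stimuli = 40, isi_s = 10, onset_s = 10,
                          amplitude = 5, habituation_decay = 0.9,
                          artifact_amplitude = 0, coupling_weight = 5,
                          coupling_delay_ms = 100) {
  list(n_stimuli = as.integer(n_stimuli), isi_s = isi_s, onset_s = onset_s,
       amplitude = amplitude, habituation_decay = habituation_decay,
       artifact_amplitude = artifact_amplitude,
       coupling_weight = coupling_weight,
       coupling_delay_ms = coupling_delay_ms)
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    stopifnot(height >= 4, width >= 4, duration_s > 0,
              fs_widefield > 0, fs_photometry >= fs_widefield,
              baseline > 0, drift_amplitude >= 0, drift_timescale_s > 0,
              noise_sd_widefield >= 0, noise_sd_photometry >= 0,
              kernel_tau_s > 0, kernel_rise_s > 0,
              kernel_rise_s < kernel_tau_s, uncoupled_photometry_sd >= 0)
    for (m in motifs)
      stopifnot(m$l_frames >= 1, m$rate_hz >= 0, m$amplitude >= 0)
    for (cp in couplings) {
      if (cp$motif < 1 || cp$motif > length(motifs))
        stop("scene_config: coupling refers to unknown motif", call. = FALSE)
      stopifnot(is.finite(cp$delay_ms), cp$weight >= 0)
    }
    if (!is.null(stimulus))
      stopifnot(stimulus$n_stimuli >= 1, stimulus$isi_s > 0,
                stimulus$habituation_decay >= 0,
                stimulus$amplitude >= 0)
  })
  invisible(cfg)
}

# truncated 2-D Gaussian blob; hard zero beyond cut*sigma so footprints of
# different templates can be made exactly disjoint
gauss_blob <- function(height, width, cy, cx, sigma, cut = 2.5) {
  y <- matrix(seq_len(height), height, width)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  d2 <- (y - cy)^2 + (x - cx)^2
  g <- exp(-d2 / (2 * sigma^2))
  g[d2 > (cut * sigma)^2] <- 0
  g
}

#' Generate motif spatial templates
#'
#' Builds the planted spatiotemporal motif templates for a configuration.
#' The `"travelling_blob"` template is a bilateral ("butterfly-like") pair
#' of sensorimotor blobs whose centroid travels strictly
#' anterior-to-posterior (increasing row index) across the L frames. The
#' `"alm_visual"` template is a static anterolateral-motor plus visual
#' pattern with a rise-and-decay temporal envelope, constructed to be
#' spatially disjoint from the travelling blob.
#'
#' @param config A [scene_config()].
#' @return A list of `height x width x L` nonnegative arrays, one per
#'   configured motif; each template's maximum equals its configured
#'   amplitude.
#' @export
generate_motif_templates <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$height; W <- config$width
  known <- c("travelling_blob", "alm_visual")
  lapply(config$motifs, function(m) {
    if (!m$template %in% known)
      stop(sprintf("generate_motif_templates: unknown template id '%s'",
                   m$template), call. = FALSE)
    L <- m$l_frames
    tpl <- array(0, c(H, W, L))
    sigma <- max(1.2, min(H, W) / 16)
    travel_rows <- c(0.30, 0.65)
    travel_cols <- c(0.34, 0.66)
    if (m$template == "travelling_blob") {
      rows <- seq(travel_rows[1] * H, travel_rows[2] * H, length.out = L)
      if (L > 1) stopifnot(all(diff(rows) > 0))
      for (l in seq_len(L)) {
        tpl[, , l] <- gauss_blob(H, W, rows[l], travel_cols[1] * W, sigma) +
          gauss_blob(H, W, rows[l], travel_cols[2] * W, sigma)
      }
    } else {
      # anterolateral motor + visual blobs, inside the bilateral cortical
      # mask but off the travelling band
      fr <- gauss_blob(H, W, 0.10 * H, 0.28 * W, sigma) +
        gauss_blob(H, W, 0.10 * H, 0.72 * W, sigma) +
        gauss_blob(H, W, 0.90 * H, 0.34 * W, sigma) +
        gauss_blob(H, W, 0.90 * H, 0.66 * W, sigma)
      # enforce exact disjointness from the travelling blob's footprint
      travel_fp <- matrix(FALSE, H, W)
      for (r in seq(travel_rows[1] * H, travel_rows[2] * H,
                    length.out = 24)) {
        travel_fp <- travel_fp |
          gauss_blob(H, W, r, travel_cols[1] * W, sigma) > 0 |
          gauss_blob(H, W, r, travel_cols[2] * W, sigma) > 0
      }
      fr[travel_fp] <- 0
      # temporal envelope: the indicator transient kernel itself, sampled at
      # the frame rate. Cortical pixels and the striatal fiber then carry
      # the same indicator kinetics, so an "attack"-mode coupling makes the
      # photometry a pure time shift of the footprint pixels.
      u <- (seq_len(L) - 1) / config$fs_widefield
      env <- exp(-u / config$kernel_tau_s) - exp(-u / config$kernel_rise_s)
      env <- if (max(env) > 0) env / max(env) else rep(1, L)
      for (l in seq_len(L)) tpl[, , l] <- fr * env[l]
    }
    mx <- max(tpl)
    if (mx > 0) tpl <- tpl * (m$amplitude / mx)
    tpl
  })
}

#' Bilateral elliptic cortical mask
#'
#' A synthetic stand-in for a registered cortical window mask: the union of
#' two hemispheric ellipses covering roughly 40% of the frame.
#'
#' @param height,width Frame size in pixels.
#' @return Logical `height x width` matrix.
#' @export
cortical_mask <- function(height, width) {
  y <- matrix(seq_len(height), height, width)
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  e1 <- ((y - 0.5 * height) / (0.46 * height))^2 +
    ((x - 0.30 * width) / (0.24 * width))^2 <= 1
  e2 <- ((y - 0.5 * height) / (0.46 * height))^2 +
    ((x - 0.70 * width) / (0.24 * width))^2 <= 1
  e1 | e2
}

# per-component sub-seeds in fixed order, so adding noise to one component
# never perturbs the draws of another
scene_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 6L)
  names(s) <- c("loadings", "wf_noise", "ph_noise", "iso_noise",
                "uncoupled", "spare")
  s
}

# homogeneous Poisson event train thinned so instances never overlap
# themselves: events closer than l_frames to the previous kept one drop out
motif_events <- function(rate_hz, duration_s, fs, l_frames) {
  n_frames <- as.integer(round(duration_s * fs))
  lam <- rate_hz * duration_s
  n_ev <- stats::rpois(1, lam)
  if (n_ev == 0) return(integer(0))
  fr <- sort(as.integer(ceiling(stats::runif(n_ev) * (n_frames - l_frames))))
  fr <- fr[fr >= 1]
  keep <- integer(0)
  last <- -l_frames
  for (f in fr) {
    if (f - last >= l_frames) {
      keep <- c(keep, f)
      last <- f
    }
  }
  keep
}

# photometry transient train: events convolved with a rise-and-decay
# indicator kernel (double exponential, default 50 ms rise / 1 s decay,
# approximating slow GCaMP kinetics). The kernel is aligned so its PEAK sits
# exactly at the configured delay after the event: the planted delay is then
# what a cross-correlation peak measures, independent of kernel asymmetry
# and of the smoothing applied when resampling onto the frame clock.
photometry_component <- function(event_times_s, delay_ms, fs_p, n_samples,
                                 tau_s, tau_rise_s = 0.05,
                                 mode = "peak") {
  out <- numeric(n_samples)
  if (length(event_times_s) == 0) return(out)
  klen <- as.integer(ceiling(6 * tau_s * fs_p))
  u <- (seq_len(klen) - 1) / fs_p
  kern <- exp(-u / tau_s) - exp(-u / tau_rise_s)
  u_peak <- if (identical(mode, "attack")) 0 else
    log(tau_s / tau_rise_s) / (1 / tau_rise_s - 1 / tau_s)
  kern <- kern / max(kern)
  for (t in event_times_s + delay_ms / 1000 - u_peak) {
    i0 <- as.integer(round(t * fs_p)) + 1L
    if (i0 > n_samples) next
    i1 <- min(n_samples, i0 + klen - 1L)
    if (i0 < 1L) {
      ks <- 2L - i0
      i0 <- 1L
      out[i0:i1] <- out[i0:i1] + kern[ks:(ks + i1 - i0)]
    } else {
      out[i0:i1] <- out[i0:i1] + kern[seq_len(i1 - i0 + 1L)]
    }
  }
  out
}

#' Generate a spontaneous synthetic session
#'
#' Builds a resting-state session: the widefield stack is
#' `baseline * (1 + drift) + sum_k template_k (*) loading_k + noise`, and
#' the 465 nm photometry channel is the baseline plus, for each coupled
#' motif, its event train delayed by the coupling delay and convolved with
#' an exponential-decay transient kernel, plus the shared drift and noise.
#' The 405 nm isosbestic channel carries the same baseline and drift with
#' independent noise but no calcium signal. Identical configurations
#' (including the seed) produce identical output.
#'
#' @param config A [scene_config()] (the `stimulus` block is ignored).
#' @return A list with `stack` ([widefield_stack()]), `photometry` (a
#'   `photometry_recording`), and `truth` (a `ground_truth` list with
#'   `motif_templates`, `motif_events`, `loadings`, `coupling_delays_ms`,
#'   `stimulus_times_s = numeric(0)`, `habituation_factors = numeric(0)`).
#' @export
generate_spontaneous_session <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  build_session(config, evoked = FALSE)
}

#' Generate an evoked synthetic session
#'
#' As [generate_spontaneous_session()], plus a stimulus block: at each
#' scheduled stimulus time a response template scaled by
#' `habituation_decay^(trial - 1)` is added to the stack, a coupled
#' transient is added to the photometry, and (optionally) a one-frame
#' artifact spike is added at the stimulus frame. Stimulus times are
#' recorded in the ground truth and emitted as an event table.
#'
#' @param config A [scene_config()] with a `stimulus` block.
#' @return As [generate_spontaneous_session()]; `photometry$events` holds
#'   the stimulus event table and `truth` gains `stimulus_times_s`,
#'   `habituation_factors` and `response_template`.
#' @export
generate_evoked_session <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(config$stimulus))
    stop("generate_evoked_session: config has no stimulus block",
         call. = FALSE)
  st <- config$stimulus
  if (st$onset_s + (st$n_stimuli - 1) * st$isi_s + 2 > config$duration_s)
    stop("generate_evoked_session: stimulus schedule exceeds the session",
         call. = FALSE)
  build_session(config, evoked = TRUE)
}

build_session <- function(config, evoked) {
  H <- config$height; W <- config$width
  fs <- config$fs_widefield; fs_p <- config$fs_photometry
  T <- as.integer(round(config$duration_s * fs))
  n_p <- as.integer(round(config$duration_s * fs_p))
  if (length(config$motifs) > 0) {
    lmax <- max(vapply(config$motifs, function(m) m$l_frames, integer(1)))
    if (T < lmax)
      stop("build_session: duration too short to contain one motif",
           call. = FALSE)
  }
  seeds <- scene_seeds(config$seed)
  templates <- generate_motif_templates(config)
  K <- length(templates)

  # motif event trains (per-motif sub-streams in fixed order)
  set.seed(seeds[["loadings"]])
  events <- vector("list", K)
  for (k in seq_len(K))
    events[[k]] <- motif_events(config$motifs[[k]]$rate_hz,
                                config$duration_s, fs,
                                config$motifs[[k]]$l_frames)
  loadings <- matrix(0, max(K, 1L), T)
  for (k in seq_len(K)) loadings[k, events[[k]]] <- 1

  # assemble stack
  tw <- (seq_len(T) - 1) / fs
  drift_w <- config$drift_amplitude *
    sin(2 * pi * tw / config$drift_timescale_s)
  base_t <- config$baseline * (1 + drift_w)
  frames <- array(0, c(H, W, T))
  for (s in seq(1L, T, by = 2000L)) {
    blk <- s:min(T, s + 1999L)
    frames[, , blk] <- rep(base_t[blk], each = H * W)
  }
  for (k in seq_len(K)) {
    L <- config$motifs[[k]]$l_frames
    for (f in events[[k]]) {
      l1 <- min(L, T - f + 1L)
      frames[, , f:(f + l1 - 1L)] <- frames[, , f:(f + l1 - 1L)] +
        templates[[k]][, , seq_len(l1)]
    }
  }

  # stimulus block
  stim_times <- numeric(0)
  hab <- numeric(0)
  resp_tpl <- NULL
  if (evoked) {
    st <- config$stimulus
    stim_times <- st$onset_s + (seq_len(st$n_stimuli) - 1) * st$isi_s
    hab <- st$habituation_decay^(seq_len(st$n_stimuli) - 1)
    resp_tpl <- response_template(H, W, fs, st$amplitude)
    Lr <- dim(resp_tpl)[3]
    for (i in seq_along(stim_times)) {
      f <- as.integer(round(stim_times[i] * fs)) + 1L
      l1 <- min(Lr, T - f + 1L)
      if (l1 < 1L) next
      frames[, , f:(f + l1 - 1L)] <- frames[, , f:(f + l1 - 1L)] +
        hab[i] * resp_tpl[, , seq_len(l1)]
      if (st$artifact_amplitude != 0)
        frames[, , f] <- frames[, , f] + st$artifact_amplitude
    }
  }

  set.seed(seeds[["wf_noise"]])
  if (config$noise_sd_widefield > 0) {
    # chunked along time so no second full-size array is ever allocated
    for (s in seq(1L, T, by = 2000L)) {
      blk <- s:min(T, s + 1999L)
      frames[, , blk] <- frames[, , blk] +
        stats::rnorm(H * W * length(blk), sd = config$noise_sd_widefield)
    }
  }

  mask <- cortical_mask(H, W)
  stack <- widefield_stack(frames, fs, mask)

  # photometry
  tp <- (seq_len(n_p) - 1) / fs_p
  drift_p <- config$drift_amplitude *
    sin(2 * pi * tp / config$drift_timescale_s)
  f465 <- config$baseline * (1 + drift_p)
  delays <- vapply(config$couplings, function(cp) cp$delay_ms, numeric(1))
  for (cp in config$couplings) {
    ev_s <- (events[[cp$motif]] - 1) / fs
    f465 <- f465 + cp$weight *
      photometry_component(ev_s, cp$delay_ms, fs_p, n_p,
                           config$kernel_tau_s, config$kernel_rise_s,
                           mode = if (is.null(cp$mode)) "peak" else cp$mode)
  }
  if (evoked) {
    st <- config$stimulus
    if (st$coupling_weight != 0) {
      # per-trial habituation applies to the photometry transients too
      comp <- numeric(n_p)
      for (i in seq_along(stim_times))
        comp <- comp + hab[i] *
          photometry_component(stim_times[i], st$coupling_delay_ms, fs_p,
                               n_p, config$kernel_tau_s,
                               config$kernel_rise_s)
      f465 <- f465 + st$coupling_weight * comp
    }
  }
  set.seed(seeds[["uncoupled"]])
  if (config$uncoupled_photometry_sd > 0) {
    # smooth uncoupled drive: white noise low-passed by the same kernel
    wn <- stats::rnorm(n_p)
    klen <- as.integer(ceiling(3 * config$kernel_tau_s * fs_p))
    kern <- exp(-(seq_len(klen) - 1) / (config$kernel_tau_s * fs_p))
    sm <- stats::filter(wn, kern, sides = 1)
    sm[is.na(sm)] <- 0
    sm <- as.numeric(sm)
    f465 <- f465 + config$uncoupled_photometry_sd * sm / stats::sd(sm)
  }
  set.seed(seeds[["ph_noise"]])
  if (config$noise_sd_photometry > 0)
    f465 <- f465 + stats::rnorm(n_p, sd = config$noise_sd_photometry)
  set.seed(seeds[["iso_noise"]])
  f405 <- config$baseline * (1 + drift_p)
  if (config$noise_sd_photometry > 0)
    f405 <- f405 + stats::rnorm(n_p, sd = config$noise_sd_photometry)

  ev_table <- if (length(stim_times) > 0)
    data.frame(time_s = stim_times, label = "stimulus") else
    data.frame(time_s = numeric(0), label = character(0))
  photometry <- photometry_recording(fp_trace(f465, fs_p),
                                     fp_trace(f405, fs_p), ev_table)

  truth <- structure(list(
    motif_templates = templates,
    motif_events = events,
    loadings = loadings,
    coupling_delays_ms = delays,
    habituation_factors = hab,
    stimulus_times_s = stim_times,
    response_template = resp_tpl,
    mask = mask
  ), class = "ground_truth")

  list(stack = stack, photometry = photometry, truth = truth,
       config = config)
}

# unilateral visual-cortex-like evoked response: posterior-lateral blob with
# a fast-rise / slower-decay time course of about one second
response_template <- function(height, width, fs, amplitude) {
  L <- as.integer(round(1.0 * fs))
  blob <- gauss_blob(height, width, 0.85 * height, 0.70 * width,
                     max(1.2, min(height, width) / 12))
  tt <- (seq_len(L) - 1) / fs
  env <- (tt / 0.1) * exp(1 - tt / 0.1)
  env <- env / max(env)
  tpl <- array(0, c(height, width, L))
  for (l in seq_len(L)) tpl[, , l] <- blob * env[l]
  tpl * (amplitude / max(tpl))
}

#' Photometry recording container
#'
#' Pairs the 465 nm (calcium-dependent) and 405 nm (isosbestic) traces with
#' the stimulus/TTL event table.
#'
#' @param f465,f405 [fp_trace()] objects with equal length and rate.
#' @param events `data.frame` with columns `time_s`, `label`.
#' @return A `photometry_recording`.
#' @export
photometry_recording <- function(f465, f405,
                                 events = data.frame(time_s = numeric(0),
                                                     label = character(0))) {
  stopifnot(inherits(f465, "fp_trace"), inherits(f405, "fp_trace"))
  if (length(f465$samples) != length(f405$samples) || f465$fs != f405$fs)
    stop("photometry_recording: channels must share length and rate",
         call. = FALSE)
  stopifnot(is.data.frame(events), all(c("time_s", "label") %in% names(events)))
  t_end <- f465$t0 + (length(f465$samples) - 1) / f465$fs
  if (nrow(events) > 0 &&
      (any(events$time_s < f465$t0) || any(events$time_s > t_end)))
    stop("photometry_recording: events outside the recording", call. = FALSE)
  structure(list(f465 = f465, f405 = f405, events = events),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %d samples @ %g Hz, %d events\n",
              length(x$f465$samples), x$f465$fs, nrow(x$events)))
  invisible(x)
}
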