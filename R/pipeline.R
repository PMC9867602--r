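#' Pipeline configuration
#'
#' Named defaults for every stage of the corticostriatal pipeline. Each
#' value is the standard parameter of the processing chain: 10-s dF/F
#' baseline window, 3-pixel disc smoothing, 0.1-12 Hz order-2 Chebyshev
#' band-pass (0.5 dB ripple), order-8 anti-aliased resampling onto the
#' frame clock, K = 8 motifs of L = 40 frames (1 s at 40 Hz),
#' lag-map validity threshold r = 0.5 with max lag 2 s, 4-SD activated-area
#' threshold on a 1-s baseline, and first/last blocks of 10 trials.
#'
#' @param ... Overrides for any default.
#' @return A named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    dff_window_s = 10,
    disc_diameter_px = 3,
    band_low_hz = 0.1,
    band_high_hz = 12,
    photometry_method = "moving_average", # or "isosbestic"
    motif_k = 8L,
    motif_l = 40L,
    motif_lambda = 0,
    motif_iter = 100L,
    max_lag_s = 2,
    r_threshold = 0.5,
    epoch_pre_s = 1,
    epoch_post_s = 2,
    n_first_last = 10L,
    area_sd_threshold = 4,
    artifact_pad = 1L,
    remove_artifacts = FALSE,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("pipeline_config: unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Preprocess a photometry recording onto the widefield frame clock
#'
#' dF/F normalization (moving-average by default, or isosbestic), the same
#' zero-phase 0.1-12 Hz band-pass applied to the cortical pixels, anti-
#' aliased resampling to the stack frame rate, and z-scoring.
#'
#' @param photometry A `photometry_recording`.
#' @param fs_out Target rate (the widefield frame rate, default 40 Hz).
#' @param config A [pipeline_config()].
#' @param t_out Optional explicit output time grid (the frame times).
#' @return A z-scored [fp_trace()] at `fs_out`.
#' @export
preprocess_photometry <- function(photometry, fs_out = 40,
                                  config = pipeline_config(),
                                  t_out = NULL) {
  stopifnot(inherits(photometry, "photometry_recording"))
  dff <- if (config$photometry_method == "isosbestic")
    isosbestic_dff(photometry$f465, photometry$f405)
  else
    moving_avg_dff(photometry$f465, window_s = config$dff_window_s)
  bp <- bandpass_filter(dff, config$band_low_hz, config$band_high_hz)
  rs <- resample_trace(bp, fs_out, t_out = t_out)
  zscore_trace(rs)
}

#' Preprocess a widefield stack
#'
#' Fixed processing order: (optional artifact removal on the raw movie,
#' when stimulus events and `remove_artifacts` are supplied), per-pixel
#' 10-s moving-average dF/F, 3-pixel disc spatial smoothing, then the
#' 0.1-12 Hz zero-phase temporal band-pass.
#'
#' @param stack A raw [widefield_stack()].
#' @param config A [pipeline_config()].
#' @param artifact_frames Optional integer frame indices to interpolate
#'   over before dF/F.
#' @return A preprocessed [widefield_stack()] with a `provenance`
#'   attribute recording the applied operations in order.
#' @export
preprocess_stack <- function(stack, config = pipeline_config(),
                             artifact_frames = NULL) {
  prov <- character(0)
  if (!is.null(artifact_frames) && length(artifact_frames) > 0) {
    stack <- remove_stim_artifact(stack, artifact_frames,
                                  pad = config$artifact_pad)
    prov <- c(prov, sprintf("remove_stim_artifact(pad=%d)",
                            config$artifact_pad))
  }
  stack <- stack_dff(stack, window_s = config$dff_window_s)
  prov <- c(prov, sprintf("stack_dff(window_s=%g)", config$dff_window_s))
  stack <- spatial_disc_smooth(stack, config$disc_diameter_px)
  prov <- c(prov, sprintf("spatial_disc_smooth(diameter=%d)",
                          config$disc_diameter_px))
  stack <- stack_bandpass(stack, config$band_low_hz, config$band_high_hz)
  prov <- c(prov, sprintf("stack_bandpass(%g-%g Hz)", config$band_low_hz,
                          config$band_high_hz))
  attr(stack, "provenance") <- prov
  stack
}

#' Run the full corticostriatal pipeline
#'
#' Orchestrates preprocessing, correlation/partial-correlation maps, the
#' lag map, seq-NMF motif discovery with motif-photometry
#' cross-correlation and map similarity, and (when stimulus events are
#' present) the evoked habituation analysis. Artifacts are written to
#' `out_dir`: a machine-readable `summary.json` (with the configuration
#' and an MD5 hash of it), map CSVs, per-motif and evoked summary CSVs,
#' PNG figures, and a log.
#'
#' @param bundle A `session_bundle` (see [load_session()]), or any list
#'   with `stack` and `photometry`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed. `NULL` skips all
#'   file output.
#' @param motifs Logical; fit seq-NMF motifs (default `TRUE`).
#' @return The summary list, invisibly.
#' @export
run_full_pipeline <- function(bundle, config = pipeline_config(),
                              out_dir = NULL, motifs = TRUE) {
  stopifnot(inherits(bundle$stack, "widefield_stack"),
            inherits(bundle$photometry, "photometry_recording"))
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }
  t_start <- proc.time()[["elapsed"]]
  events <- bundle$photometry$events
  have_events <- nrow(events) > 0

  say("preprocessing widefield stack (%d x %d x %d)",
      dim(bundle$stack)[1], dim(bundle$stack)[2], dim(bundle$stack)[3])
  artifact_frames <- NULL
  if (have_events && isTRUE(config$remove_artifacts))
    artifact_frames <- as.integer(
      round((events$time_s - bundle$stack$t0) * bundle$stack$fs)) + 1L
  stack <- preprocess_stack(bundle$stack, config, artifact_frames)

  say("preprocessing photometry (%d samples @ %g Hz)",
      length(bundle$photometry$f465$samples), bundle$photometry$f465$fs)
  trace <- preprocess_photometry(bundle$photometry, bundle$stack$fs, config,
                                 t_out = frame_times(bundle$stack))

  say("global signal and correlation maps")
  gsig <- zscore_trace(global_signal(stack))
  cmap <- correlation_map(stack, trace)
  pmap <- partial_correlation_map(stack, trace, gsig)

  say("lag map (max lag %g s, r threshold %g)", config$max_lag_s,
      config$r_threshold)
  lmap <- lag_map(stack, trace, config$max_lag_s, config$r_threshold)
  lsum <- lag_map_summary(lmap)

  motif_summary <- NULL
  mset <- NULL
  if (isTRUE(motifs)) {
    say("seq-NMF motif discovery (K=%d, L=%d, %d iterations)",
        config$motif_k, config$motif_l, config$motif_iter)
    X <- stack_matrix(stack, masked_only = TRUE)
    X[X < 0] <- 0 # seq-NMF requires nonnegative input; clip negative dF/F
    mset <- seqnmf_fit(X, K = config$motif_k, L = config$motif_l,
                       lambda = config$motif_lambda,
                       n_iter = config$motif_iter, seed = config$seed)
    mx <- motif_photometry_xcorr(mset, trace, config$max_lag_s)
    sim <- motif_map_similarity(mset, cmap)
    motif_summary <- merge(mx, sim, by = "motif")
    motif_summary$empty <- empty_motifs(mset)[motif_summary$motif]
    motif_summary <- motif_summary[order(-ifelse(is.na(motif_summary$peak_r),
                                                 -Inf, motif_summary$peak_r)), ]
  }

  evoked_summary <- NULL
  if (have_events) {
    say("evoked analysis (%d events)", nrow(events))
    ep_tr <- extract_epochs(gsig, events$time_s, config$epoch_pre_s,
                            config$epoch_post_s)
    ev <- trial_average_first_last(ep_tr, config$n_first_last)
    ep_st <- extract_epochs(stack, events$time_s, config$epoch_pre_s,
                            config$epoch_post_s)
    evs <- trial_average_first_last(ep_st, config$n_first_last)
    area_first <- activated_area(evs$mean_first, evs$onset_index,
                                 stack$mask, config$area_sd_threshold)
    area_last <- activated_area(evs$mean_last, evs$onset_index,
                                stack$mask, config$area_sd_threshold)
    evoked_summary <- data.frame(
      n_trials = dim(ep_tr$epochs)[1],
      n_dropped = ep_tr$n_dropped,
      amplitude_first = ev$amplitude_first,
      amplitude_last = ev$amplitude_last,
      habituation_ratio = ev$habituation_ratio,
      activated_area_first = area_first$count,
      activated_area_last = area_last$count
    )
  } else {
    say("no events: evoked stage skipped")
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(as.character(cfg_json), tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  summary <- list(
    version = as.character(utils::packageVersion("mesofiber")),
    config = config,
    config_md5 = cfg_hash,
    provenance = attr(stack, "provenance"),
    lag_map = as.list(lsum),
    motifs = if (!is.null(motif_summary))
      lapply(split(motif_summary, seq_len(nrow(motif_summary))), as.list),
    evoked = if (!is.null(evoked_summary)) as.list(evoked_summary),
    elapsed_s = proc.time()[["elapsed"]] - t_start
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_map_csv(cmap$values, file.path(out_dir, "correlation_map.csv"))
    write_map_csv(pmap$values,
                  file.path(out_dir, "partial_correlation_map.csv"))
    write_map_csv(lmap$lags, file.path(out_dir, "lag_map.csv"))
    write_map_csv(lmap$peak_r, file.path(out_dir, "lag_map_peak_r.csv"))
    if (!is.null(motif_summary))
      utils::write.csv(motif_summary, file.path(out_dir, "motifs.csv"),
                       row.names = FALSE)
    if (!is.null(evoked_summary))
      utils::write.csv(evoked_summary,
                       file.path(out_dir, "evoked_summary.csv"),
                       row.names = FALSE)
    grDevices::png(file.path(out_dir, "correlation_map.png"), 480, 480)
    plot(cmap); grDevices::dev.off()
    grDevices::png(file.path(out_dir, "partial_correlation_map.png"),
                   480, 480)
    plot(pmap); grDevices::dev.off()
    grDevices::png(file.path(out_dir, "lag_map.png"), 480, 480)
    plot(lmap); grDevices::dev.off()
    if (!is.null(mset)) {
      for (k in seq_len(mset$K)) {
        grDevices::png(file.path(out_dir, sprintf("motif_%02d.png", k)),
                       960, 480)
        plot_motif(mset, k, stack$mask)
        grDevices::dev.off()
      }
    }
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }
  say("done in %.1f s", summary$elapsed_s)
  invisible(summary)
}
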