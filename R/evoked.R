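#' Extract stimulus-locked epochs
#'
#' Cuts a trace or a widefield stack into per-trial windows around each
#' event time (`pre_s` before to `post_s` after onset). Events whose window
#' would extend past either end of the recording are dropped with a warning
#' and counted.
#'
#' @param data An [fp_trace()] or [widefield_stack()].
#' @param event_times Sorted numeric vector of stimulus onset times in
#'   seconds.
#' @param pre_s Baseline window before onset in seconds (default 1).
#' @param post_s Window after onset in seconds.
#' @return An `epoch_set`: for traces, `epochs` is an `n_trials x n_samples`
#'   matrix; for stacks, an `n_trials x H x W x n_samples` array. Also
#'   carries `pre_s`, `post_s`, `fs`, `event_times` (used), `n_dropped`,
#'   `onset_index` (first post-stimulus sample), and `mask` for stacks.
#' @export
extract_epochs <- function(data, event_times, pre_s = 1, post_s = 2) {
  if (is.unsorted(event_times))
    stop("extract_epochs: event times must be sorted", call. = FALSE)
  is_stack <- inherits(data, "widefield_stack")
  if (!is_stack && !inherits(data, "fp_trace"))
    stop("extract_epochs: data must be an fp_trace or widefield_stack",
         call. = FALSE)
  fs <- data$fs
  t0 <- data$t0
  n <- if (is_stack) dim(data$frames)[3] else length(data$samples)
  npre <- as.integer(round(pre_s * fs))
  npost <- as.integer(round(post_s * fs))
  len <- npre + npost + 1L
  onset_idx <- as.integer(round((event_times - t0) * fs)) + 1L
  keep <- onset_idx - npre >= 1L & onset_idx + npost <= n
  if (!all(keep))
    warning(sprintf("extract_epochs: dropped %d event(s) at the recording edges",
                    sum(!keep)))
  if (!any(keep))
    stop("extract_epochs: no usable events", call. = FALSE)
  oi <- onset_idx[keep]
  nt <- length(oi)
  if (is_stack) {
    d <- dim(data$frames)
    ep <- array(NA_real_, c(nt, d[1], d[2], len))
    for (i in seq_len(nt))
      ep[i, , , ] <- data$frames[, , (oi[i] - npre):(oi[i] + npost)]
    mask <- data$mask
  } else {
    ep <- t(vapply(oi, function(j) data$samples[(j - npre):(j + npost)],
                   numeric(len)))
    mask <- NULL
  }
  structure(list(epochs = ep, pre_s = pre_s, post_s = post_s, fs = fs,
                 event_times = event_times[keep], n_dropped = sum(!keep),
                 onset_index = npre + 1L, mask = mask),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  nt <- dim(x$epochs)[1]
  cat(sprintf("<epoch_set> %d trials, -%g..+%g s @ %g Hz (%d dropped)\n",
              nt, x$pre_s, x$post_s, x$fs, x$n_dropped))
  invisible(x)
}

#' Subtract each epoch's pre-stimulus baseline
#'
#' Normalizes every epoch to its own baseline: the mean over the
#' pre-stimulus window is subtracted (per trial; per pixel for stack
#' epochs).
#'
#' @param epochs An `epoch_set`.
#' @return An `epoch_set` with baseline-subtracted epochs.
#' @export
baseline_normalize <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  pre <- seq_len(epochs$onset_index - 1L)
  if (length(pre) < 1L)
    stop("baseline_normalize: no pre-stimulus samples", call. = FALSE)
  ep <- epochs$epochs
  if (length(dim(ep)) == 2L) {
    ep <- ep - rowMeans(ep[, pre, drop = FALSE])
  } else {
    bl <- apply(ep[, , , pre, drop = FALSE], c(1, 2, 3), mean)
    ep <- sweep(ep, c(1, 2, 3), bl, "-")
  }
  out <- epochs
  out$epochs <- ep
  out
}

#' First-10 versus last-10 trial averages
#'
#' Averages the first `n` and last `n` trials elementwise and measures each
#' average's peak amplitude after subtracting its own pre-stimulus baseline
#' mean -- the habituation comparison (a declining last/first ratio means
#' the response habituates).
#'
#' @param epochs An `epoch_set` of trace epochs (trials x samples) or stack
#'   epochs.
#' @param n Trials per block (default 10); requires `n_trials >= 2n`.
#' @return An `evoked_summary`: `mean_first`/`mean_last` (average epochs),
#'   `amplitude_first`/`amplitude_last` (baseline-subtracted peak of the
#'   spatial-mean response for stacks, of the trace for traces),
#'   `habituation_ratio`, and `n`.
#' @export
trial_average_first_last <- function(epochs, n = 10) {
  stopifnot(inherits(epochs, "epoch_set"))
  ep <- epochs$epochs
  nt <- dim(ep)[1]
  if (nt < 2 * n)
    stop("trial_average_first_last: need at least 2n trials", call. = FALSE)
  first_i <- seq_len(n)
  last_i <- (nt - n + 1L):nt
  pre <- seq_len(epochs$onset_index - 1L)
  if (length(dim(ep)) == 2L) {
    mean_first <- colMeans(ep[first_i, , drop = FALSE])
    mean_last <- colMeans(ep[last_i, , drop = FALSE])
    tr_first <- mean_first
    tr_last <- mean_last
  } else {
    mean_first <- apply(ep[first_i, , , , drop = FALSE], c(2, 3, 4), mean)
    mean_last <- apply(ep[last_i, , , , drop = FALSE], c(2, 3, 4), mean)
    msk <- if (is.null(epochs$mask)) matrix(TRUE, dim(ep)[2], dim(ep)[3])
           else epochs$mask
    tr_first <- apply(mean_first, 3, function(fr) mean(fr[msk]))
    tr_last <- apply(mean_last, 3, function(fr) mean(fr[msk]))
  }
  amp <- function(tr) max(tr[-pre] - mean(tr[pre]))
  a1 <- amp(tr_first)
  a2 <- amp(tr_last)
  structure(list(mean_first = mean_first, mean_last = mean_last,
                 amplitude_first = a1, amplitude_last = a2,
                 habituation_ratio = if (a1 != 0) a2 / a1 else NA_real_,
                 n = n, pre_s = epochs$pre_s, fs = epochs$fs,
                 onset_index = epochs$onset_index, mask = epochs$mask),
            class = "evoked_summary")
}

#' @export
print.evoked_summary <- function(x, ...) {
  cat(sprintf(
    "<evoked_summary> first %d vs last %d trials: amplitude %.4g -> %.4g (ratio %.3f)\n",
    x$n, x$n, x$amplitude_first, x$amplitude_last, x$habituation_ratio))
  invisible(x)
}

#' Activated cortical area
#'
#' Counts masked pixels whose trial-averaged evoked response exceeds
#' `mean + n_sd * SD` of that pixel's pre-stimulus baseline (baseline = the
#' 1-s window before stimulation by default). The response statistic is the
#' post-stimulus peak per pixel (`mode = "peak"`); `mode = "any"` instead
#' requires any single supra-threshold frame.
#'
#' Pixels with zero baseline variance fall back to the global (across-pixel)
#' baseline SD and are flagged.
#'
#' @param avg_epoch An H x W x n_samples trial-averaged epoch stack (e.g.
#'   `mean_first` from [trial_average_first_last()]).
#' @param onset_index First post-stimulus sample along the third axis.
#' @param mask Logical H x W cortical mask (default all pixels).
#' @param n_sd Threshold in baseline SDs (default 4).
#' @param mode `"peak"` (default) or `"any"`.
#' @return A list: `count` (activated pixels), `active` (H x W logical),
#'   `n_zero_var` (pixels using the global SD fallback).
#' @export
activated_area <- function(avg_epoch, onset_index, mask = NULL, n_sd = 4,
                           mode = c("peak", "any")) {
  mode <- match.arg(mode)
  d <- dim(avg_epoch)
  if (length(d) != 3L)
    stop("activated_area: avg_epoch must be H x W x samples", call. = FALSE)
  if (onset_index < 2L || onset_index > d[3])
    stop("activated_area: baseline window is empty", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  pre <- seq_len(onset_index - 1L)
  post <- onset_index:d[3]
  X <- matrix(avg_epoch, d[1] * d[2], d[3])
  mu <- rowMeans(X[, pre, drop = FALSE])
  sdv <- sqrt(rowMeans(X[, pre, drop = FALSE]^2) - mu^2)
  sdv[sdv < 0] <- 0
  mvec <- as.vector(mask)
  zero_var <- sdv == 0 & mvec
  if (any(zero_var)) {
    gsd <- sqrt(mean((X[mvec, pre] - rowMeans(X[mvec, pre, drop = FALSE]))^2))
    sdv[zero_var] <- gsd
  }
  thr <- mu + n_sd * sdv
  postX <- X[, post, drop = FALSE]
  exceed <- if (mode == "peak") {
    apply(postX, 1, max) > thr
  } else {
    rowSums(postX > thr) > 0
  }
  active <- matrix(exceed & mvec, d[1], d[2])
  list(count = sum(active), active = active, n_zero_var = sum(zero_var))
}

#' Preprocess a behavior motion trace
#'
#' Low-pass filters a FaceMap-style motion-energy trace with a centered 1-s
#' moving average, then z-scores it, matching the conditioning applied
#' before correlating behavior with neural signals.
#'
#' @param motion An [fp_trace()].
#' @param window_s Moving-average window in seconds (default 1).
#' @return A z-scored, smoothed [fp_trace()].
#' @export
behavior_preproc <- function(motion, window_s = 1) {
  stopifnot(inherits(motion, "fp_trace"))
  h <- floor(window_s * motion$fs / 2)
  sm <- moving_mean_vec(motion$samples, h)
  fp_trace(zscore_vec(sm), motion$fs, motion$t0, method = "behavior")
}
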