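#' Widefield cortical movie
#'
#' Container for a mesoscale cortical calcium movie: an `H x W x T` array of
#' fluorescence values, the frame rate, and a binary cortical mask. Pixels
#' outside the mask are carried along as zeros and excluded from every
#' statistic.
#'
#' @param frames Numeric `H x W x T` array (`T >= 2`).
#' @param fs Frame rate in Hz.
#' @param mask Logical (or 0/1) `H x W` matrix with at least one `TRUE`
#'   pixel. Defaults to all pixels.
#' @param t0 Time of the first frame in seconds.
#' @return An object of class `widefield_stack`.
#' @examples
#' st <- widefield_stack(array(1, c(4, 4, 10)), fs = 40)
#' @export
widefield_stack <- function(frames, fs, mask = NULL, t0 = 0) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L || d[3] < 2L)
    stop("widefield_stack: frames must be an H x W x T array with T >= 2",
         call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  mask <- matrix(as.logical(mask), d[1], d[2])
  if (!any(mask))
    stop("widefield_stack: mask has no TRUE pixel", call. = FALSE)
  if (!identical(dim(mask), d[1:2]))
    stop("widefield_stack: mask shape does not match frames", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0)
    stop("widefield_stack: fs must be positive", call. = FALSE)
  structure(
    list(frames = frames, fs = fs, mask = mask, t0 = as.numeric(t0)),
    class = "widefield_stack"
  )
}

#' @export
print.widefield_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<widefield_stack> %d x %d x %d @ %g Hz, %d masked pixels\n",
              d[1], d[2], d[3], x$fs, sum(x$mask)))
  invisible(x)
}

#' @export
dim.widefield_stack <- function(x) dim(x$frames)

#' Frame times of a stack
#' @param stack A [widefield_stack()].
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(stack) {
  stopifnot(inherits(stack, "widefield_stack"))
  stack$t0 + (seq_len(dim(stack$frames)[3]) - 1) / stack$fs
}

#' Flatten a stack to a pixels-by-time matrix
#'
#' @param stack A [widefield_stack()].
#' @param masked_only Drop rows outside the cortical mask (e.g. to build
#'   the seq-NMF input matrix).
#' @return A numeric matrix, pixels x frames.
#' @export
stack_matrix <- function(stack, masked_only = FALSE) {
  d <- dim(stack$frames)
  m <- matrix(stack$frames, d[1] * d[2], d[3])
  if (masked_only) m[as.vector(stack$mask), , drop = FALSE] else m
}

#' Per-pixel dF/F with a moving-average baseline
#'
#' Applies the moving-average dF/F normalization (see [moving_avg_dff()]) to
#' every pixel's time series: F0 is a centered moving mean (default 10 s,
#' truncated at the edges) and the output is `(F - F0)/F0`. Pixels outside
#' the mask are set to zero.
#'
#' @param stack A [widefield_stack()] of raw fluorescence.
#' @param window_s Baseline window in seconds.
#' @return A [widefield_stack()] of dF/F values.
#' @export
stack_dff <- function(stack, window_s = 10) {
  stopifnot(inherits(stack, "widefield_stack"))
  w <- window_s * stack$fs
  if (w < 1) stop("stack_dff: window shorter than one frame", call. = FALSE)
  h <- as.integer(floor(w / 2))
  d <- dim(stack$frames)
  P <- d[1] * d[2]; T <- d[3]
  X <- matrix(stack$frames, P, T)
  # cumulative sums along time, column by column to bound memory churn
  S <- X + 0 # force a distinct copy
  for (t in 2:T) S[, t] <- S[, t - 1] + X[, t]
  out <- matrix(0, P, T)
  f0min <- rep(Inf, P)
  for (t in seq_len(T)) {
    hi <- min(T, t + h)
    lo <- max(1L, t - h)
    f0 <- (S[, hi] - (if (lo > 1L) S[, lo - 1L] else 0)) / (hi - lo + 1)
    f0min <- pmin(f0min, f0)
    out[, t] <- f0
  }
  rm(S)
  mvec <- as.vector(stack$mask)
  bad <- which(mvec & f0min <= 0)
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], d[1:2])
    stop(sprintf(
      "stack_dff: non-positive baseline at masked pixel (row %d, col %d)",
      rc[1], rc[2]), call. = FALSE)
  }
  # (X - F0) / F0, column-wise in place to avoid another P x T temporary
  for (t in seq_len(T)) out[, t] <- (X[, t] - out[, t]) / out[, t]
  rm(X)
  out[!mvec, ] <- 0
  dim(out) <- d
  widefield_stack(out, stack$fs, stack$mask, stack$t0)
}

# offsets of a disc kernel: pixel centers within diameter/2 of the center
disc_offsets <- function(diameter_px) {
  r <- diameter_px / 2
  h <- floor(diameter_px / 2)
  g <- expand.grid(dy = -h:h, dx = -h:h)
  g[sqrt(g$dy^2 + g$dx^2) <= r, , drop = FALSE]
}

# reflect indices 1..n at the borders (EBImage/scipy "reflect" style,
# edge pixel duplicated: ... 2 1 | 1 2 ... n-1 n | n n-1 ...)
reflect_idx <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

#' Spatial disc smoothing
#'
#' Smooths every frame with a normalized moving disc filter: the kernel
#' contains all pixels whose center lies within `diameter/2` of the kernel
#' center (for diameter 3 this is the full 3x3 neighborhood, diagonals
#' included), with equal weights summing to one. Edges use reflected
#' padding, so a constant frame is left unchanged and spatial mean is
#' approximately preserved.
#'
#' @param stack A [widefield_stack()].
#' @param diameter_px Odd disc diameter in pixels (default 3).
#' @return A smoothed [widefield_stack()].
#' @export
spatial_disc_smooth <- function(stack, diameter_px = 3) {
  stopifnot(inherits(stack, "widefield_stack"))
  if (diameter_px < 1 || diameter_px %% 2 == 0)
    stop("spatial_disc_smooth: diameter must be odd and >= 1", call. = FALSE)
  off <- disc_offsets(diameter_px)
  d <- dim(stack$frames)
  out <- array(0, d)
  for (i in seq_len(nrow(off))) {
    ih <- reflect_idx(seq_len(d[1]) + off$dy[i], d[1])
    iw <- reflect_idx(seq_len(d[2]) + off$dx[i], d[2])
    out <- out + stack$frames[ih, iw, , drop = FALSE]
  }
  out <- out / nrow(off)
  widefield_stack(out, stack$fs, stack$mask, stack$t0)
}

#' Temporal band-pass of a stack
#'
#' Applies [bandpass_filter()] along time at every masked pixel (zero-phase
#' Chebyshev Type I, order 2, 0.5 dB ripple). Unmasked pixels are set to 0.
#'
#' @inheritParams bandpass_filter
#' @param stack A [widefield_stack()].
#' @return A filtered [widefield_stack()].
#' @export
stack_bandpass <- function(stack, low = 0.1, high = 12, order = 2,
                           ripple_db = 0.5) {
  stopifnot(inherits(stack, "widefield_stack"))
  fs <- stack$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop("stack_bandpass: need 0 < low < high < fs/2", call. = FALSE)
  flt <- signal::cheby1(order, ripple_db, c(low, high) / (fs / 2),
                        type = "pass")
  d <- dim(stack$frames)
  X <- matrix(stack$frames, d[1] * d[2], d[3])
  out <- matrix(0, d[1] * d[2], d[3])
  for (p in which(as.vector(stack$mask)))
    out[p, ] <- filtfilt_zp(flt$b, flt$a, X[p, ])
  widefield_stack(array(out, d), fs, stack$mask, stack$t0)
}

#' Remove stimulation artifacts by linear interpolation
#'
#' Replaces each contiguous run of artifact frames, extended by `pad` frames
#' on both sides, with per-pixel linear interpolation between the nearest
#' clean frames. Intended for the raw (pre-dF/F) movie, where a stimulus LED
#' flash contaminates one or a few frames.
#'
#' @param stack A [widefield_stack()] of raw fluorescence.
#' @param artifact_frames Integer frame indices contaminated by the artifact.
#' @param pad Extra frames to excise on each side of every run (default 1).
#' @return A [widefield_stack()] with artifact frames interpolated.
#' @export
remove_stim_artifact <- function(stack, artifact_frames, pad = 1) {
  stopifnot(inherits(stack, "widefield_stack"))
  if (length(artifact_frames) == 0) return(stack)
  T <- dim(stack$frames)[3]
  af <- sort(unique(as.integer(artifact_frames)))
  if (any(af < 1L | af > T))
    stop("remove_stim_artifact: artifact frames outside the recording",
         call. = FALSE)
  # contiguous runs, then pad
  runs <- split(af, cumsum(c(1L, diff(af) > 1L)))
  d <- dim(stack$frames)
  out <- stack$frames
  for (r in runs) {
    lo <- min(r) - pad
    hi <- max(r) + pad
    if (lo <= 1L || hi >= T)
      stop("remove_stim_artifact: artifact run touches the recording edge",
           call. = FALSE)
    a <- out[, , lo - 1L]
    b <- out[, , hi + 1L]
    for (k in lo:hi) {
      w <- (k - (lo - 1L)) / (hi + 1L - (lo - 1L))
      out[, , k] <- (1 - w) * a + w * b
    }
  }
  widefield_stack(out, stack$fs, stack$mask, stack$t0)
}

#' Global cortical activity
#'
#' Spatial mean over all masked cortical pixels, per frame. This is the
#' signal regressed out to form partial correlation maps.
#'
#' @param stack A [widefield_stack()].
#' @return An [fp_trace()] at the stack frame rate.
#' @export
global_signal <- function(stack) {
  stopifnot(inherits(stack, "widefield_stack"))
  X <- stack_matrix(stack, masked_only = TRUE)
  fp_trace(colMeans(X), stack$fs, stack$t0, method = "global_signal")
}
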