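#' dF/F by isosbestic baseline fit
#'
#' Fits the calcium-insensitive isosbestic channel (405 nm) to the
#' calcium-dependent channel (465 nm) by ordinary least squares,
#' `F0 = a * f405 + b`, treats the fit as baseline fluorescence F0, and
#' returns `(f465 - F0) / F0`. Because any movement or bleaching artifact
#' appears in both excitation channels, this removes it while leaving
#' calcium transients (which the 405 channel does not see) in the output.
#'
#' @param f465 Calcium-dependent channel, an [fp_trace()].
#' @param f405 Isosbestic channel, an [fp_trace()] with the same length and
#'   sampling rate.
#' @return An [fp_trace()] of dimensionless dF/F values, `method =
#'   "isosbestic"`.
#' @examples
#' t <- seq(0, 10, by = 1e-2)
#' f405 <- fp_trace(10 + sin(2 * pi * 0.05 * t), fs = 100)
#' f465 <- fp_trace(2 * f405$samples, fs = 100)
#' dff <- isosbestic_dff(f465, f405)
#' @export
isosbestic_dff <- function(f465, f405) {
  stopifnot(inherits(f465, "fp_trace"), inherits(f405, "fp_trace"))
  if (length(f465$samples) != length(f405$samples) || f465$fs != f405$fs)
    stop("isosbestic_dff: channels must share length and sampling rate",
         call. = FALSE)
  x <- f405$samples
  y <- f465$samples
  if (stats::var(x) == 0)
    stop("isosbestic_dff: isosbestic channel is constant; fit is degenerate",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  f0 <- fit$fitted.values
  if (any(f0 <= 0))
    stop("isosbestic_dff: fitted baseline is non-positive", call. = FALSE)
  fp_trace((y - f0) / f0, f465$fs, f465$t0, method = "isosbestic")
}

#' dF/F by moving-average baseline
#'
#' Uses a centered moving average (default 10 s) of the raw trace as the
#' baseline F0 and returns `(F - F0) / F0`. This is the same normalization
#' applied per-pixel to the widefield movie, so cortical and photometry
#' signals are treated identically and no relative lag is introduced. The
#' window shrinks (is truncated) at the trace edges so F0 is defined at
#' every sample.
#'
#' The division by F0 makes the output dimensionless and comparable to the
#' isosbestic method; a subtract-only variant (`divide = FALSE`) returning
#' `F - F0` is available.
#'
#' @param trace An [fp_trace()] of raw fluorescence.
#' @param window_s Moving-average window in seconds (default 10).
#' @param divide If `TRUE` (default) return `(F - F0)/F0`, else `F - F0`.
#' @return An [fp_trace()], `method = "moving_average"`.
#' @examples
#' tr <- fp_trace(rep(10, 100) + rnorm(100, sd = 0.1), fs = 10)
#' dff <- moving_avg_dff(tr)
#' @export
moving_avg_dff <- function(trace, window_s = 10, divide = TRUE) {
  stopifnot(inherits(trace, "fp_trace"))
  w <- window_s * trace$fs
  if (w < 1)
    stop("moving_avg_dff: window shorter than one sample", call. = FALSE)
  h <- floor(w / 2)
  f0 <- moving_mean_vec(trace$samples, h)
  if (divide && any(f0 <= 0))
    stop("moving_avg_dff: moving-average baseline is non-positive",
         call. = FALSE)
  out <- if (divide) (trace$samples - f0) / f0 else trace$samples - f0
  fp_trace(out, trace$fs, trace$t0, method = "moving_average")
}
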