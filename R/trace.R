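#' Sampled fluorescence trace
#'
#' Lightweight container for a regularly sampled 1-D signal, used for both raw
#' photometry channels (465 nm calcium-dependent, 405 nm isosbestic) and
#' derived signals (dF/F, global cortical activity, behavior motion energy).
#'
#' @param samples Numeric vector of sample values (arbitrary fluorescence
#'   units, or dimensionless for dF/F and z-scored traces). Must be finite and
#'   of length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param method Optional character tag recording how the trace was derived
#'   (e.g. `"moving_average"` or `"isosbestic"` for dF/F traces); kept for
#'   provenance.
#'
#' @return An object of class `fp_trace`: a list with elements `samples`,
#'   `fs`, `t0` and `method`.
#' @examples
#' tr <- fp_trace(sin(2 * pi * 2 * seq(0, 5, by = 1 / 40)), fs = 40)
#' trace_times(tr)[1:5]
#' @export
fp_trace <- function(samples, fs, t0 = 0, method = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("fp_trace: need at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("fp_trace: samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fp_trace: fs must be a single positive number", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, t0 = as.numeric(t0), method = method),
    class = "fp_trace"
  )
}

#' @export
print.fp_trace <- function(x, ...) {
  cat(sprintf(
    "<fp_trace> %d samples @ %g Hz (%.1f s)%s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    if (is.null(x$method)) "" else paste0(" [", x$method, "]")
  ))
  invisible(x)
}

#' @export
length.fp_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace An [fp_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "fp_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

#' @export
plot.fp_trace <- function(x, ..., xlab = "time (s)", ylab = "value",
                          type = "l") {
  graphics::plot(trace_times(x), x$samples, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Z-score a trace
#'
#' Centers to mean zero and scales to unit population standard deviation
#' (1/N denominator). A constant trace maps to all zeros rather than an error,
#' so degenerate pixels or flat control channels propagate harmlessly.
#'
#' @param trace An [fp_trace()].
#' @return An [fp_trace()] with mean 0 and population SD 1 (or all zeros).
#' @examples
#' z <- zscore_trace(fp_trace(c(1, 2, 3), fs = 1))
#' mean(z$samples)
#' @export
zscore_trace <- function(trace) {
  stopifnot(inherits(trace, "fp_trace"))
  z <- zscore_vec(trace$samples)
  fp_trace(z, trace$fs, trace$t0, method = trace$method)
}

# population z-score; constant vector -> zeros
zscore_vec <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

#' Signal-to-noise ratio in decibels
#'
#' Ratio of the summed squared magnitude of the signal to that of the noise,
#' `10 * log10(sum(s^2) / sum(n^2))`. This is the broadband sum-of-squares
#' definition, not a harmonic-distortion SNR.
#'
#' @param signal,noise [fp_trace()] objects or numeric vectors.
#' @return SNR in dB. If the noise has zero energy, `Inf` is returned with a
#'   warning.
#' @examples
#' snr_db(c(10), c(1)) # 20 dB
#' @export
snr_db <- function(signal, noise) {
  s <- if (inherits(signal, "fp_trace")) signal$samples else as.numeric(signal)
  n <- if (inherits(noise, "fp_trace")) noise$samples else as.numeric(noise)
  if (length(s) == 0 || length(n) == 0)
    stop("snr_db: signal and noise must be non-empty", call. = FALSE)
  ss <- sum(s^2)
  nn <- sum(n^2)
  if (nn == 0) {
    warning("snr_db: noise energy is zero; returning Inf")
    return(Inf)
  }
  10 * log10(ss / nn)
}
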