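# Zero-phase IIR filtering.
#
# signal::filtfilt applies no padding, so sharp low-frequency filters leave
# long startup transients inside the data. The wrapper below pads with an
# odd (point-reflected) extension whose length is derived from the slowest
# filter pole, filters forward and backward with signal::filter, and trims.

# pad length: a fixed multiple of the slowest pole's time constant, capped at
# the signal length - 1 (the longest odd reflection available)
zp_pad_length <- function(a, n) {
  p <- tryCatch(Mod(polyroot(rev(a))), error = function(e) numeric(0))
  p <- p[p < 1 & p > 0]
  tc <- if (length(p) == 0) 1 else -1 / log(max(p))
  as.integer(min(n - 1, max(3 * (length(a) - 1), ceiling(12 * tc))))
}

# forward-backward filtering with odd-reflection padding; b, a filter coefs
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  if (n < 4) stop("filtfilt_zp: signal too short", call. = FALSE)
  np <- zp_pad_length(a, n)
  ext <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filter(b, a, ext)
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(np + 1):(np + n)]
}

# squared magnitude response of the forward-backward filter at frequency
# f (Hz) for sampling rate fs; |H(e^{jw})|^2
filtfilt_gain <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- vapply(seq_along(f), function(i) {
    num <- sum(b * z[i]^(0:(length(b) - 1)))
    den <- sum(a * z[i]^(0:(length(a) - 1)))
    Mod(num / den)
  }, numeric(1))
  h^2
}

#' Zero-phase Chebyshev band-pass filter
#'
#' Temporal band-pass with a Chebyshev Type I design (order 2, 0.5 dB
#' passband ripple by default, matching the widefield/photometry processing
#' chain), applied forward and backward so the net filter has zero phase and
#' the effective magnitude response is the square of the single-pass
#' response. Zero-phase filtering preserves event times, which matters
#' because downstream lag maps compare timing across signals; the identical
#' filter is applied to cortical pixels and photometry so no relative lag is
#' introduced.
#'
#' @param trace An [fp_trace()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Chebyshev design order (2 gives a 4th-order band-pass).
#' @param ripple_db Passband ripple in dB.
#' @return Filtered [fp_trace()] of the same length.
#' @examples
#' tr <- fp_trace(rnorm(2000), fs = 40)
#' bp <- bandpass_filter(tr)
#' @export
bandpass_filter <- function(trace, low = 0.1, high = 12, order = 2,
                            ripple_db = 0.5) {
  stopifnot(inherits(trace, "fp_trace"))
  fs <- trace$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stop(sprintf(
      "bandpass_filter: need 0 < low < high < fs/2 (got %g, %g at fs %g)",
      low, high, fs), call. = FALSE)
  flt <- signal::cheby1(order, ripple_db, c(low, high) / (fs / 2),
                        type = "pass")
  y <- filtfilt_zp(flt$b, flt$a, trace$samples)
  fp_trace(y, fs, trace$t0, method = trace$method)
}

#' Anti-aliased resampling onto a lower sampling rate
#'
#' Decimation in the style used to bring ~1 kHz photometry onto the 40 Hz
#' widefield frame clock: an order-8 Chebyshev Type I low-pass anti-aliasing
#' filter (cutoff `0.8 * fs_out / 2`, 0.05 dB ripple) applied zero-phase,
#' followed by linear interpolation onto the target time grid. When
#' `fs_out == fs` the input is returned unchanged (identical grid, no
#' filtering).
#'
#' @param trace An [fp_trace()].
#' @param fs_out Target sampling rate in Hz, `fs_out <= fs`.
#' @param t_out Optional explicit output time grid in seconds (e.g. widefield
#'   frame times); defaults to a grid at `fs_out` spanning the input.
#' @return An [fp_trace()] sampled at `fs_out`.
#' @examples
#' tr <- fp_trace(sin(2 * pi * 2 * seq(0, 10, by = 1e-3)), fs = 1000)
#' lo <- resample_trace(tr, 40)
#' @export
resample_trace <- function(trace, fs_out = 40, t_out = NULL) {
  stopifnot(inherits(trace, "fp_trace"))
  fs <- trace$fs
  if (fs_out > fs)
    stop("resample_trace: fs_out must not exceed the input rate",
         call. = FALSE)
  if (is.null(t_out)) {
    t_in <- trace_times(trace)
    t_out <- seq(trace$t0, t_in[length(t_in)], by = 1 / fs_out)
  }
  if (fs_out == fs && length(t_out) == length(trace$samples) &&
      max(abs(t_out - trace_times(trace))) < 1e-9 / fs)
    return(trace)
  flt <- signal::cheby1(8, 0.05, 0.8 * (fs_out / 2) / (fs / 2), type = "low")
  y <- filtfilt_zp(flt$b, flt$a, trace$samples)
  yi <- stats::approx(trace_times(trace), y, xout = t_out, rule = 2)$y
  fp_trace(yi, fs_out, t_out[1], method = trace$method)
}

# centered moving mean with truncated (shrinking) windows at the edges;
# half-width h samples each side
moving_mean_vec <- function(x, half_width) {
  n <- length(x)
  h <- as.integer(half_width)
  if (h <= 0) return(x)
  s <- cumsum(x)
  i <- seq_len(n)
  hi <- pmin(n, i + h)
  lo <- pmax(1L, i - h)
  (s[hi] - c(0, s)[lo]) / (hi - lo + 1)
}
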