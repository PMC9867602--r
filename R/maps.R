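#' Pixel-wise correlation map
#'
#' Pearson correlation between each masked cortical pixel's time series and
#' the striatal photometry trace (already resampled onto the frame clock).
#' Unmasked pixels are `NA`.
#'
#' @param stack A [widefield_stack()] (preprocessed dF/F).
#' @param trace An [fp_trace()] at the stack frame rate, same length as the
#'   stack's time axis.
#' @return A `correlation_map` object: list with `values` (H x W matrix of
#'   Pearson r, `NA` outside the mask), `kind = "full"`, and `mask`.
#' @export
correlation_map <- function(stack, trace) {
  stopifnot(inherits(stack, "widefield_stack"), inherits(trace, "fp_trace"))
  d <- dim(stack$frames)
  if (length(trace$samples) != d[3])
    stop("correlation_map: trace length does not match the stack",
         call. = FALSE)
  X <- stack_matrix(stack, masked_only = TRUE)
  r <- pixel_cor(X, trace$samples)
  vals <- matrix(NA_real_, d[1], d[2])
  vals[stack$mask] <- r
  structure(list(values = vals, kind = "full", mask = stack$mask),
            class = "correlation_map")
}

# row-wise Pearson correlation of matrix X (pixels x T) with vector y
pixel_cor <- function(X, y) {
  T <- ncol(X)
  xm <- rowMeans(X)
  yz <- y - mean(y)
  sy <- sqrt(sum(yz^2))
  num <- as.vector(X %*% yz) - 0 # rowMeans already handled via centering y
  sx <- sqrt(rowSums(X^2) - T * xm^2)
  r <- num / (sx * sy)
  r[!is.finite(r)] <- 0
  pmin(1, pmax(-1, r))
}

#' Partial correlation map controlling for the global signal
#'
#' Pearson correlation of each pixel with the photometry trace after
#' regressing out the global cortical activity, computed by the closed form
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`.
#' Pixels whose time series is (anti)perfectly correlated with the global
#' signal have zero residual variance; they are set to 0 and flagged.
#'
#' @inheritParams correlation_map
#' @param global The global cortical activity, an [fp_trace()] of matching
#'   length (see [global_signal()]).
#' @return A `correlation_map` with `kind = "partial"` and an added logical
#'   `degenerate` matrix marking zero-residual pixels.
#' @export
partial_correlation_map <- function(stack, trace, global) {
  stopifnot(inherits(stack, "widefield_stack"), inherits(trace, "fp_trace"),
            inherits(global, "fp_trace"))
  d <- dim(stack$frames)
  if (length(trace$samples) != d[3] || length(global$samples) != d[3])
    stop("partial_correlation_map: trace/global length mismatch",
         call. = FALSE)
  g <- global$samples
  if (stats::var(g) == 0)
    stop("partial_correlation_map: global signal is constant", call. = FALSE)
  X <- stack_matrix(stack, masked_only = TRUE)
  r_xy <- pixel_cor(X, trace$samples)
  r_xz <- pixel_cor(X, g)
  r_yz <- stats::cor(trace$samples, g)
  den2 <- (1 - r_xz^2) * (1 - r_yz^2)
  degen <- abs(r_xz) >= 1 - 1e-12 | den2 <= 0
  r <- (r_xy - r_xz * r_yz) / sqrt(pmax(den2, .Machine$double.eps))
  r[degen] <- 0
  r <- pmin(1, pmax(-1, r))
  vals <- matrix(NA_real_, d[1], d[2])
  vals[stack$mask] <- r
  dmat <- matrix(FALSE, d[1], d[2])
  dmat[stack$mask] <- degen
  structure(list(values = vals, kind = "partial", mask = stack$mask,
                 degenerate = dmat),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map:%s> %d x %d, r in [%.2f, %.2f]\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.correlation_map <- function(x, zlim = c(-1, 1), ...) {
  img <- t(x$values[nrow(x$values):1, , drop = FALSE])
  graphics::image(img, zlim = zlim, asp = nrow(x$values) / ncol(x$values),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE, main = paste(x$kind, "correlation map"), ...)
  invisible(x)
}

#' Cross-correlation lag between two traces
#'
#' Scans integer-sample lags in `[-max_lag, max_lag]` and, at each lag,
#' computes the Pearson correlation over the overlapping segment
#' (re-estimating means and SDs per lag, so |r| <= 1 exactly). Returns the
#' lag maximizing the signed correlation.
#'
#' Sign convention: negative lag means the first trace leads. If
#' `b(t) = a(t - d)` (a leads by d) the returned lag is `-d`.
#'
#' @param a,b [fp_trace()] objects with equal sampling rate and length.
#' @param max_lag Maximum |lag| in seconds (`max_lag * fs >= 1`).
#' @return A list with `lag` (seconds), `peak_r`, and the full `r` vector
#'   with its `lags` (seconds).
#' @examples
#' x <- rnorm(500)
#' a <- fp_trace(x, fs = 40)
#' b <- fp_trace(c(rep(0, 12), x[1:488]), fs = 40) # a leads by 0.3 s
#' xcorr_lag(a, b, max_lag = 1)$lag
#' @export
xcorr_lag <- function(a, b, max_lag) {
  stopifnot(inherits(a, "fp_trace"), inherits(b, "fp_trace"))
  if (a$fs != b$fs || length(a$samples) != length(b$samples))
    stop("xcorr_lag: traces must share fs and length", call. = FALSE)
  fs <- a$fs
  M <- as.integer(round(max_lag * fs))
  if (M < 1) stop("xcorr_lag: max_lag shorter than one sample", call. = FALSE)
  n <- length(a$samples)
  if (n - M < 10)
    stop("xcorr_lag: overlap at extreme lags is degenerate (< 10 samples)",
         call. = FALSE)
  lags <- (-M):M
  r <- vapply(lags, function(tau) {
    if (tau >= 0) {
      ia <- (tau + 1L):n
      ib <- 1L:(n - tau)
    } else {
      ia <- 1L:(n + tau)
      ib <- (1L - tau):n
    }
    sa <- stats::sd(a$samples[ia])
    sb <- stats::sd(b$samples[ib])
    if (sa == 0 || sb == 0) return(NA_real_)
    stats::cor(a$samples[ia], b$samples[ib])
  }, numeric(1))
  if (all(is.na(r)))
    stop("xcorr_lag: all lags degenerate (constant input?)", call. = FALSE)
  i <- which.max(r)
  list(lag = lags[i] / fs, peak_r = r[i], r = r, lags = lags / fs)
}

#' Pixel-wise cross-correlation lag map
#'
#' Applies the [xcorr_lag()] scan to every masked pixel against the
#' photometry trace. Pixels whose peak correlation falls below
#' `r_threshold` are marked invalid (the gray regions of a lag map:
#' correlation too low, no detectable peak). All lags are integer multiples
#' of the frame interval; no sub-sample interpolation is attempted.
#'
#' @inheritParams correlation_map
#' @param max_lag Maximum |lag| in seconds (default 2).
#' @param r_threshold Validity threshold on the peak correlation
#'   (default 0.5).
#' @param chunk_px Number of pixels processed per block (memory control).
#' @return A `lag_map` object: `lags` (H x W seconds, negative = cortex
#'   leads; `NA` outside mask), `peak_r`, `valid`, `r_threshold`, `max_lag`,
#'   `mask`.
#' @export
lag_map <- function(stack, trace, max_lag = 2, r_threshold = 0.5,
                    chunk_px = 1024L) {
  stopifnot(inherits(stack, "widefield_stack"), inherits(trace, "fp_trace"))
  d <- dim(stack$frames)
  T <- d[3]
  if (length(trace$samples) != T)
    stop("lag_map: trace length does not match the stack", call. = FALSE)
  fs <- stack$fs
  M <- as.integer(round(max_lag * fs))
  if (M < 1) stop("lag_map: max_lag shorter than one frame", call. = FALSE)
  if (T - M < 10)
    stop("lag_map: overlap at extreme lags is degenerate", call. = FALSE)
  lags <- (-M):M
  nl <- length(lags)
  b <- trace$samples
  # B[t, j] = b[t - lag_j] over the valid overlap, 0 elsewhere, so that
  # X %*% B gives all per-pixel cross sums in one GEMM
  B <- matrix(0, T, nl)
  sb <- cumsum(b)
  sbb <- cumsum(b^2)
  Sb <- Sbb <- nn <- numeric(nl)
  alo <- ahi <- integer(nl)
  for (j in seq_len(nl)) {
    tau <- lags[j]
    if (tau >= 0) { ia <- (tau + 1L):T; ib <- 1L:(T - tau) }
    else { ia <- 1L:(T + tau); ib <- (1L - tau):T }
    B[ia, j] <- b[ib]
    Sb[j] <- sb[ib[length(ib)]] - (if (ib[1] > 1L) sb[ib[1] - 1L] else 0)
    Sbb[j] <- sbb[ib[length(ib)]] - (if (ib[1] > 1L) sbb[ib[1] - 1L] else 0)
    nn[j] <- length(ia)
    alo[j] <- ia[1]; ahi[j] <- ia[length(ia)]
  }
  varb <- Sbb - Sb^2 / nn
  mvec <- which(as.vector(stack$mask))
  P <- length(mvec)
  Xall <- matrix(stack$frames, d[1] * d[2], T)
  best_lag <- best_r <- numeric(P)
  for (s in seq(1L, P, by = chunk_px)) {
    e <- min(P, s + chunk_px - 1L)
    X <- Xall[mvec[s:e], , drop = FALSE]
    C <- X %*% B
    SX <- X
    for (t in 2:T) SX[, t] <- SX[, t - 1] + X[, t]
    SXX <- X^2
    for (t in 2:T) SXX[, t] <- SXX[, t - 1] + X[, t]^2
    R <- matrix(NA_real_, nrow(X), nl)
    for (j in seq_len(nl)) {
      sx <- SX[, ahi[j]] - (if (alo[j] > 1L) SX[, alo[j] - 1L] else 0)
      sxx <- SXX[, ahi[j]] - (if (alo[j] > 1L) SXX[, alo[j] - 1L] else 0)
      varx <- sxx - sx^2 / nn[j]
      den <- sqrt(pmax(varx, 0) * max(varb[j], 0))
      R[, j] <- (C[, j] - sx * Sb[j] / nn[j]) / den
    }
    R[!is.finite(R)] <- -Inf
    jbest <- max.col(R, ties.method = "first")
    idx <- cbind(seq_len(nrow(R)), jbest)
    best_lag[s:e] <- lags[jbest] / fs
    best_r[s:e] <- R[idx]
  }
  lmat <- rmat <- matrix(NA_real_, d[1], d[2])
  vmat <- matrix(FALSE, d[1], d[2])
  lmat[mvec] <- best_lag
  rmat[mvec] <- best_r
  vmat[mvec] <- is.finite(best_r) & best_r >= r_threshold
  structure(list(lags = lmat, peak_r = rmat, valid = vmat,
                 r_threshold = r_threshold, max_lag = max_lag,
                 mask = stack$mask, fs = fs),
            class = "lag_map")
}

#' @export
print.lag_map <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf(
    "<lag_map> %d x %d, %d valid pixels (r >= %.2f), mean lag %.3f s\n",
    nrow(x$lags), ncol(x$lags), nv, x$r_threshold,
    if (nv > 0) mean(x$lags[x$valid]) else NA_real_))
  invisible(x)
}

#' @export
plot.lag_map <- function(x, ...) {
  v <- x$lags
  v[!x$valid] <- NA
  img <- t(v[nrow(v):1, , drop = FALSE])
  graphics::image(img, zlim = c(-x$max_lag, x$max_lag),
                  asp = nrow(v) / ncol(v),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = "photometry lag map (s)", ...)
  invisible(x)
}

#' Summarize a lag map
#'
#' Valid-pixel count and mean lag, overall and split into anterior (upper
#' rows) and posterior (lower rows) halves of the field of view.
#'
#' @param lmap A `lag_map` from [lag_map()].
#' @return A one-row `data.frame`.
#' @export
lag_map_summary <- function(lmap) {
  stopifnot(inherits(lmap, "lag_map"))
  H <- nrow(lmap$lags)
  ant <- seq_len(floor(H / 2))
  post <- setdiff(seq_len(H), ant)
  mean_or_na <- function(rows) {
    v <- lmap$valid[rows, , drop = FALSE]
    l <- lmap$lags[rows, , drop = FALSE]
    if (any(v)) mean(l[v]) else NA_real_
  }
  data.frame(
    n_valid = sum(lmap$valid),
    n_masked = sum(lmap$mask),
    mean_lag_s = if (any(lmap$valid)) mean(lmap$lags[lmap$valid]) else NA_real_,
    mean_lag_anterior_s = mean_or_na(ant),
    mean_lag_posterior_s = mean_or_na(post)
  )
}
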