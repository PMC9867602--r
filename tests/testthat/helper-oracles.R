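# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# Pearson correlation by the direct formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# sliding Pearson correlation over all integer lags; returns the lag (in
# seconds) with the maximum correlation. Convention: r(tau) compares
# a(t) with b(t - tau), so a leading b gives a negative best lag.
oracle_xcorr <- function(a, b, fs, max_lag_s) {
  M <- round(max_lag_s * fs)
  n <- length(a)
  lags <- (-M):M
  r <- sapply(lags, function(tau) {
    if (tau >= 0) {
      ia <- (tau + 1):n; ib <- 1:(n - tau)
    } else {
      ia <- 1:(n + tau); ib <- (1 - tau):n
    }
    suppressWarnings(stats::cor(a[ia], b[ib]))
  })
  i <- which.max(r)
  list(lag = lags[i] / fs, peak_r = r[i], r = r)
}

# OLS fit of y ~ 1 + x via explicitly solved normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  A <- matrix(c(n, sum(x), sum(x), sum(x^2)), 2, 2)
  coef <- solve(A, c(sum(y), sum(x * y)))
  list(intercept = coef[1], slope = coef[2],
       fitted = coef[1] + coef[2] * x)
}

# truncated centered moving mean by direct looping
oracle_moving_mean <- function(x, half_width) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    mean(x[max(1, i - half_width):min(n, i + half_width)])
  })
}

# partial correlation via residual regression: regress z out of x and y,
# correlate the residuals
oracle_partial_cor <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# direct convolutional reconstruction sum_k sum_l W[,k,l] H[k, t-l+1]
oracle_reconstruct <- function(W, H) {
  P <- dim(W)[1]; K <- dim(W)[2]; L <- dim(W)[3]; T <- ncol(H)
  out <- matrix(0, P, T)
  for (k in seq_len(K))
    for (l in seq_len(L))
      for (t in seq_len(T)) {
        tt <- t - l + 1
        if (tt >= 1) out[, t] <- out[, t] + W[, k, l] * H[k, tt]
      }
  out
}

# band-limited smooth test signal (moving-average filtered white noise)
smooth_noise <- function(n, seed = 1, width = 9) {
  set.seed(seed)
  x <- as.numeric(stats::filter(rnorm(n + 2 * width), rep(1, width) / width,
                                sides = 2))
  x <- x[!is.na(x)][seq_len(n)]
  x
}
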