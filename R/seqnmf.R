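# Convolutional sequential NMF (seq-NMF) for spatiotemporal motif discovery.
#
# Model: X (P pixels x T frames, nonnegative) ~ sum_l W[,,l] %*% shift(H, l-1)
# with W (P x K x L) >= 0 motif templates and H (K x T) >= 0 loadings.
# Objective: ||X - Xhat||_F^2 + lambda * sum_{k != k'} [(W~'X) S H']_{kk'}
# where (W~'X) is the transpose-convolution of W with X and S smooths over a
# (2L-1)-frame window: the x-ortho penalty discourages two factors from
# explaining the same data at nearby times.
#
# Implementation note: all heavy quantities are expressed through the lagged
# loading matrix H_aug (KL x T, rows = shifted copies of H) and the flattened
# template matrix W_flat (P x KL), so each multiplicative update costs a few
# dense matrix products and the P x T reconstruction is never materialized.

# per-motif shift bringing the center of mass of W's frame energies to the
# middle of the L-frame window (positive = shift template later)
recenter_shift <- function(Wf, P, K, L) {
  W <- array(Wf, c(P, K, L))
  vapply(seq_len(K), function(k) {
    e <- apply(matrix(W[, k, ], P, L)^2, 2, sum)
    if (sum(e) == 0) return(0L)
    com <- sum(e * seq_len(L)) / sum(e)
    # half-up rounding: a template sitting half a frame off-center still
    # re-centers instead of sticking (round() would round 0.5 to 0)
    as.integer(floor((L + 1) / 2 - com + 0.5))
  }, integer(1))
}

# shift template k by sh[k] frames within its window (zero-filled,
# truncating at the window edge) and counter-shift its loading row
apply_shifts <- function(Wf, H, sh, P, K, L) {
  W <- array(Wf, c(P, K, L))
  T <- ncol(H)
  for (k in seq_len(K)) {
    s <- sh[k]
    if (s == 0L) next
    Wk <- matrix(W[, k, ], P, L)
    # shifted-in frames get a small positive floor: multiplicative updates
    # cannot regrow exact zeros
    Wk2 <- matrix(1e-6 * max(Wk), P, L)
    if (s > 0L) {
      Wk2[, (s + 1L):L] <- Wk[, 1:(L - s), drop = FALSE]
      hk <- H[k, ]
      H[k, ] <- c(hk[(s + 1L):T], rep(0, s))
    } else {
      s <- -s
      Wk2[, 1:(L - s)] <- Wk[, (s + 1L):L, drop = FALSE]
      hk <- H[k, ]
      H[k, ] <- c(rep(0, s), hk[1:(T - s)])
    }
    W[, k, ] <- Wk2
  }
  list(Wf = matrix(W, P, K * L), H = H)
}

# H_aug[(l-1)*K + k, t] = H[k, t - l + 1]
build_h_aug <- function(H, L) {
  K <- nrow(H); T <- ncol(H)
  A <- matrix(0, K * L, T)
  for (l in seq_len(L)) {
    rows <- ((l - 1L) * K + 1L):(l * K)
    A[rows, l:T] <- H[, 1:(T - l + 1L), drop = FALSE]
  }
  A
}

# fold a KL x T matrix G into K x T: out[k, t] = sum_l G[(l-1)K + k, t + l - 1]
fold_lags <- function(G, K, L) {
  T <- ncol(G)
  out <- matrix(0, K, T)
  for (l in seq_len(L)) {
    rows <- ((l - 1L) * K + 1L):(l * K)
    out[, 1:(T - l + 1L)] <- out[, 1:(T - l + 1L)] +
      G[rows, l:T, drop = FALSE]
  }
  out
}

# per-row sliding sum with an ones(width) kernel, 'same' zero-padded
row_boxsum <- function(M, width) {
  h <- (width - 1L) %/% 2L
  T <- ncol(M)
  out <- M
  for (k in seq_len(nrow(M))) {
    s <- cumsum(M[k, ])
    i <- seq_len(T)
    hi <- pmin(T, i + h)
    lo <- pmax(1L, i - h)
    out[k, ] <- s[hi] - c(0, s)[lo]
  }
  out
}

#' Fit a sequential convolutional NMF
#'
#' Decomposes a nonnegative pixels-by-time matrix into K spatiotemporal
#' motifs of L frames each, `X ~ sum_l W[,,l] H(t - l + 1)`, by seeded
#' multiplicative updates minimizing the squared Frobenius reconstruction
#' error plus `lambda` times a cross-factor orthogonality penalty
#' (penalizing distinct motifs that explain the same data at nearby times).
#' At `lambda = 0` the updates are monotone: the recorded objective never
#' increases.
#'
#' After fitting, each motif is normalized to per-motif maximum 1 with the
#' scale absorbed into its loading row, and (by default) onset-aligned:
#' convolutional factorizations are invariant to shifting a template within
#' its L-frame window while counter-shifting its loading, so templates are
#' rotated so that their first energetic frame sits at window position 1 and
#' loadings mark motif onset. This removes an arbitrary per-fit time offset
#' from downstream loading-lag estimates.
#'
#' @param X Nonnegative numeric matrix, P pixels x T frames (e.g. masked,
#'   rectified dF/F).
#' @param K Number of motifs.
#' @param L Motif length in frames (default 40, i.e. 1 s at 40 Hz).
#' @param lambda Cross-orthogonality penalty weight (default 0).
#' @param n_iter Number of multiplicative update iterations (default 100).
#' @param seed Integer seed for the random nonnegative initialization.
#' @param align `"onset"` (default) or `"none"`; see Details.
#' @param onset_frac Energy fraction defining a motif's onset frame.
#' @param recenter If `TRUE` (default), re-center each motif's energy in its
#'   L-frame window after every iteration (counter-shifting its loading).
#'   Multiplicative updates cannot move mass past a window edge once it
#'   locks to zero, so without re-centering fits regularly stall in
#'   truncated local optima. Re-centering preserves the reconstruction
#'   except for content truncated at a window edge, so it can transiently
#'   raise the objective; set `recenter = FALSE` to obtain the strictly
#'   monotone pure multiplicative updates.
#' @return A `motif_set`: `W` (P x K x L), `H` (K x T), `L`, `lambda`,
#'   `objective` (length `n_iter + 1`, initial value first), `seed`.
#' @export
seqnmf_fit <- function(X, K, L = 40L, lambda = 0, n_iter = 100L,
                       seed = 1L, align = c("onset", "none"),
                       onset_frac = 0.05, recenter = TRUE) {
  align <- match.arg(align)
  if (!is.matrix(X)) stop("seqnmf_fit: X must be a matrix", call. = FALSE)
  if (any(X < 0)) stop("seqnmf_fit: X must be nonnegative", call. = FALSE)
  P <- nrow(X); T <- ncol(X)
  K <- as.integer(K); L <- as.integer(L)
  if (K < 1L || L < 1L || n_iter < 1L)
    stop("seqnmf_fit: K, L, n_iter must be >= 1", call. = FALSE)
  if (K * L > T)
    stop("seqnmf_fit: K * L exceeds the number of frames", call. = FALSE)
  eps <- .Machine$double.eps
  set.seed(seed)
  mx <- max(X)
  if (mx == 0) mx <- 1
  Wf <- matrix(stats::runif(P * K * L) * mx, P, K * L)
  H <- matrix(stats::runif(K * T) * mx / sqrt(T), K, T)
  offdiag <- matrix(1, K, K) - diag(K)
  normX2 <- sum(X^2)
  obj <- numeric(n_iter + 1L)

  objective <- function(A, Haug, G) {
    # ||X - Xhat||^2 via <X,Xhat> = <A, Haug>, <Xhat,Xhat> = <G, Haug Haug'>
    Q <- tcrossprod(Haug)
    err <- normX2 - 2 * sum(A * Haug) + sum(G * Q)
    pen <- 0
    if (lambda > 0) {
      WTX <- fold_lags(A, K, L)
      PK <- row_boxsum(WTX, 2L * L - 1L) %*% t(H)
      pen <- lambda * sum(PK * offdiag)
    }
    err + pen
  }

  Haug <- build_h_aug(H, L)
  for (it in seq_len(n_iter)) {
    A <- crossprod(Wf, X)          # KL x T
    G <- crossprod(Wf)             # KL x KL
    if (it == 1L) obj[1L] <- objective(A, Haug, G)
    # ---- H update ----
    WTX <- fold_lags(A, K, L)
    WTXhat <- fold_lags(G %*% Haug, K, L)
    dRdH <- if (lambda > 0)
      lambda * (offdiag %*% row_boxsum(WTX, 2L * L - 1L)) else 0
    H <- H * WTX / (WTXhat + dRdH + eps)
    Haug <- build_h_aug(H, L)
    # ---- W update ----
    XHT <- X %*% t(Haug)           # P x KL
    Q <- tcrossprod(Haug)          # KL x KL
    XhatHT <- Wf %*% Q
    if (lambda > 0) {
      B <- X %*% t(row_boxsum(Haug, 2L * L - 1L))
      dRdW <- matrix(0, P, K * L)
      for (l in seq_len(L)) {
        cols <- ((l - 1L) * K + 1L):(l * K)
        dRdW[, cols] <- lambda * (B[, cols, drop = FALSE] %*% offdiag)
      }
    } else dRdW <- 0
    Wf <- Wf * XHT / (XhatHT + dRdW + eps)
    if (recenter && it < n_iter) {
      sh <- recenter_shift(Wf, P, K, L)
      if (any(sh != 0L)) {
        res <- apply_shifts(Wf, H, sh, P, K, L)
        Wf <- res$Wf
        H <- res$H
        Haug <- build_h_aug(H, L)
      }
    }
    # objective after the full iteration
    A2 <- crossprod(Wf, X)
    G2 <- crossprod(Wf)
    obj[it + 1L] <- objective(A2, Haug, G2)
  }
  W <- array(Wf, c(P, K, L))
  # normalize: per-motif max 1, scale into H
  for (k in seq_len(K)) {
    m <- max(W[, k, ])
    if (m > 0) {
      W[, k, ] <- W[, k, ] / m
      H[k, ] <- H[k, ] * m
    }
  }
  if (align == "onset") {
    for (k in seq_len(K)) {
      e <- apply(W[, k, , drop = FALSE]^2, 3, sum)
      if (max(e) == 0) next
      s <- which(e >= onset_frac * max(e))[1] - 1L
      if (s > 0L) {
        Wk <- matrix(W[, k, ], P, L)
        Wk2 <- matrix(0, P, L)
        Wk2[, 1:(L - s)] <- Wk[, (s + 1L):L, drop = FALSE]
        W[, k, ] <- Wk2
        hk <- H[k, ]
        H[k, ] <- c(rep(0, s), hk[1:(T - s)])
      }
    }
  }
  structure(list(W = W, H = H, K = K, L = L, lambda = lambda,
                 objective = obj, seed = seed),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf(
    "<motif_set> K = %d motifs, L = %d frames, %d pixels; final objective %.4g\n",
    x$K, x$L, dim(x$W)[1], x$objective[length(x$objective)]))
  invisible(x)
}

#' Reconstruct the movie from a motif set
#'
#' Computes `sum_k sum_l W[, k, l] * H[k, t - l + 1]` with zero padding
#' outside the recording.
#'
#' @param motifs A `motif_set` from [seqnmf_fit()].
#' @return A P x T nonnegative matrix.
#' @export
reconstruct <- function(motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  d <- dim(motifs$W)
  # array (P, K, L) flattens with k fastest after p, so the column index of
  # Wf is (l-1)*K + k -- the same convention build_h_aug uses for its rows
  Wf <- matrix(motifs$W, d[1], d[2] * d[3])
  Wf %*% build_h_aug(motifs$H, d[3])
}

#' Cross-correlation of motif loadings with the photometry trace
#'
#' Z-scores each motif's temporal loading and the striatal trace, then runs
#' the [xcorr_lag()] scan per motif. Motifs whose loading is constant (e.g.
#' empty factors) are flagged degenerate and given `NA` lag and peak.
#'
#' @param motifs A `motif_set`.
#' @param trace An [fp_trace()] at the frame rate of the fitted movie, with
#'   length equal to `ncol(motifs$H)`.
#' @param max_lag Maximum |lag| in seconds.
#' @return A `data.frame` with one row per motif (`motif`, `lag_s`,
#'   `peak_r`, `degenerate`), sorted by `peak_r` descending.
#' @export
motif_photometry_xcorr <- function(motifs, trace, max_lag = 2) {
  stopifnot(inherits(motifs, "motif_set"), inherits(trace, "fp_trace"))
  K <- motifs$K
  T <- ncol(motifs$H)
  if (length(trace$samples) != T)
    stop("motif_photometry_xcorr: trace length does not match loadings",
         call. = FALSE)
  if (stats::sd(trace$samples) == 0) {
    warning("motif_photometry_xcorr: trace is constant; all motifs degenerate")
    return(data.frame(motif = seq_len(K), lag_s = NA_real_,
                      peak_r = NA_real_, degenerate = TRUE))
  }
  zt <- fp_trace(zscore_vec(trace$samples), trace$fs, trace$t0)
  res <- lapply(seq_len(K), function(k) {
    h <- motifs$H[k, ]
    if (stats::sd(h) == 0)
      return(data.frame(motif = k, lag_s = NA_real_, peak_r = NA_real_,
                        degenerate = TRUE))
    zh <- fp_trace(zscore_vec(h), trace$fs, trace$t0)
    xc <- xcorr_lag(zh, zt, max_lag)
    data.frame(motif = k, lag_s = xc$lag, peak_r = xc$peak_r,
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-ifelse(is.na(out$peak_r), -Inf, out$peak_r)), , drop = FALSE]
}

#' Spatial similarity of motifs to a correlation map
#'
#' Pearson correlation, over masked pixels, between each motif's temporal
#' max-projection and a correlation map. High similarity identifies the
#' map-like (corticostriatally coupled) motif class.
#'
#' @param motifs A `motif_set` fitted on the masked pixels of the same mask
#'   as `cmap`.
#' @param cmap A `correlation_map`.
#' @return A `data.frame` with `motif` and `similarity`.
#' @export
motif_map_similarity <- function(motifs, cmap) {
  stopifnot(inherits(motifs, "motif_set"), inherits(cmap, "correlation_map"))
  mv <- cmap$values[cmap$mask]
  if (dim(motifs$W)[1] != length(mv))
    stop("motif_map_similarity: motif pixels do not match the map mask",
         call. = FALSE)
  if (stats::sd(mv) == 0)
    stop("motif_map_similarity: correlation map is constant", call. = FALSE)
  sim <- vapply(seq_len(motifs$K), function(k) {
    proj <- apply(motifs$W[, k, , drop = FALSE], 1, max)
    if (stats::sd(proj) == 0) return(NA_real_)
    stats::cor(proj, mv)
  }, numeric(1))
  data.frame(motif = seq_len(motifs$K), similarity = sim)
}

#' Identify near-empty motifs
#'
#' Motifs whose loading-row energy is below `tol` times the largest row's
#' energy carry no repeating structure and are excluded from reports (they
#' remain in the returned `motif_set`).
#'
#' @param motifs A `motif_set`.
#' @param tol Relative energy threshold (default 1e-6).
#' @return Logical vector, `TRUE` for empty motifs.
#' @export
empty_motifs <- function(motifs, tol = 1e-6) {
  stopifnot(inherits(motifs, "motif_set"))
  e <- rowSums(motifs$H^2)
  if (max(e) == 0) return(rep(TRUE, motifs$K))
  e < tol * max(e)
}

#' Montage plot of a motif
#'
#' Draws the L frames of one motif left-to-right, top-to-bottom.
#'
#' @param motifs A `motif_set`.
#' @param k Motif index.
#' @param mask The H x W mask the motif pixels refer to.
#' @param ncol Frames per montage row.
#' @export
plot_motif <- function(motifs, k, mask, ncol = 8) {
  stopifnot(inherits(motifs, "motif_set"))
  L <- motifs$L
  nrow_m <- ceiling(L / ncol)
  old <- graphics::par(mfrow = c(nrow_m, ncol), mar = c(0.2, 0.2, 0.2, 0.2))
  on.exit(graphics::par(old))
  zmax <- max(motifs$W[, k, ], 1e-12)
  for (l in seq_len(L)) {
    fr <- matrix(0, nrow(mask), ncol(mask))
    fr[mask] <- motifs$W[, k, l]
    img <- t(fr[nrow(fr):1, , drop = FALSE])
    graphics::image(img, zlim = c(0, zmax), axes = FALSE,
                    col = grDevices::hcl.colors(32, "inferno"))
  }
  invisible(motifs)
}
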