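## Small linear-algebra helpers shared by the subspace identifier and the
## Gaussian-process imputer. Kept internal.

#' Moore-Penrose pseudo-inverse via SVD
#' @param x numeric matrix
#' @param tol singular values below tol * max(sv) are treated as zero
#' @return the pseudo-inverse of `x`
#' @keywords internal
#' @noRd
pinv <- function(x, tol = .Machine$double.eps^0.75) {
  x <- as.matrix(x)
  s <- svd(x)
  keep <- s$d > tol * max(s$d[1], .Machine$double.xmin)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Spectral radius of a square matrix
#' @keywords internal
#' @noRd
spectral_radius <- function(a) {
  if (length(a) == 0L) return(0)
  max(Mod(eigen(a, only.values = TRUE)$values))
}

#' Block-Hankel matrix of a multichannel signal
#'
#' Stacks `nrows` block rows of the (channels x N) signal `x`: block row r
#' holds samples r .. r + ncols - 1.
#' @keywords internal
#' @noRd
block_hankel <- function(x, nrows, ncols) {
  x <- as.matrix(x)              # channels x N
  nc <- nrow(x)
  h <- matrix(0, nrows * nc, ncols)
  for (r in seq_len(nrows)) {
    h[(r - 1L) * nc + seq_len(nc), ] <- x[, r:(r + ncols - 1L), drop = FALSE]
  }
  h
}

#' Stabilising solution of the discrete algebraic Riccati equation
#'
#' Solves P = A P A' + Q - (A P C' + S)(C P C' + R)^{-1}(A P C' + S)' by
#' fixed-point iteration, returning the Kalman predictor gain
#' K = (A P C' + S)(C P C' + R)^{-1}. Orders here are <= 10 so the simple
#' iteration is adequate.
#' @keywords internal
#' @noRd
dare_kalman_gain <- function(A, C, Q, R, S, max_iter = 2000L, tol = 1e-10) {
  nx <- nrow(A)
  P <- diag(nx)
  for (it in seq_len(max_iter)) {
    APC <- A %*% P %*% t(C) + S
    denom <- C %*% P %*% t(C) + R
    Kt <- APC %*% pinv(denom)
    Pn <- A %*% P %*% t(A) + Q - Kt %*% t(APC)
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol * (1 + max(abs(P)))) {
      P <- Pn
      break
    }
    P <- Pn
    if (!all(is.finite(P))) return(NULL)
  }
  APC <- A %*% P %*% t(C) + S
  denom <- C %*% P %*% t(C) + R
  K <- APC %*% pinv(denom)
  if (!all(is.finite(K))) return(NULL)
  K
}

#' Clip the eigenvalues of a square matrix into the stability disk
#'
#' Eigenvalues with modulus above `rho` are radially shrunk to `rho`; the
#' matrix is rebuilt from its (possibly complex) eigendecomposition. Falls
#' back to uniform scaling if the eigenvector basis is degenerate.
#' @keywords internal
#' @noRd
stabilize_matrix <- function(A, rho = 0.98) {
  if (spectral_radius(A) <= rho) return(A)
  e <- tryCatch(eigen(A), error = function(err) NULL)
  if (!is.null(e) && all(is.finite(Mod(e$values)))) {
    lam <- e$values
    bad <- Mod(lam) > rho
    lam[bad] <- lam[bad] * (rho / Mod(lam[bad]))
    An <- tryCatch(Re(e$vectors %*% diag(lam, length(lam)) %*%
                        solve(e$vectors)),
                   error = function(err) NULL)
    if (!is.null(An) && all(is.finite(An)) && spectral_radius(An) <= rho + 1e-6)
      return(An)
  }
  A * (rho / spectral_radius(A))
}

#' Linear convolution via FFT
#'
#' Full-length linear convolution of `x` with kernel `h`; used for FIR
#' filtering of long 1-250 Hz channel vectors where direct convolution is
#' too slow.
#' @keywords internal
#' @noRd
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2L)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                       stats::fft(c(h, rep(0, nfft - length(h)))),
                     inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Windowed-sinc low-pass FIR design (Hamming window)
#'
#' @param order filter order (number of taps - 1); forced even so the
#'   group delay order/2 is an integer number of samples
#' @param cutoff normalized cutoff in cycles/sample (0, 0.5)
#' @return numeric vector of taps normalized to unit DC gain
#' @keywords internal
#' @noRd
fir_lowpass <- function(order, cutoff) {
  stopifnot(cutoff > 0, cutoff < 0.5)
  if (order %% 2L == 1L) order <- order + 1L
  n <- 0:order
  m <- n - order / 2
  h <- 2 * cutoff * sinc(2 * cutoff * m)
  w <- 0.54 - 0.46 * cos(2 * pi * n / order)
  h <- h * w
  h / sum(h)
}

#' @keywords internal
#' @noRd
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Linear interpolation over NA runs (ends extended constant)
#' @keywords internal
#' @noRd
na_interp <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) return(x)
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}
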