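#' Maximum-Likelihood Expectation Maximization reconstruction
#'
#' Multiplicative EM update for the Poisson emission model
#' `p ~ Poisson(H x + r)`:
#' \deqn{x^{t+1} = x^t \odot (H^T (p \oslash (H x^t + r))) \oslash (H^T 1).}
#' Denominators are clamped at `eps` before elementwise division; the
#' iterate stays nonnegative and pixels with zero sensitivity (or
#' outside the field-of-view disk, where the initial image is zero)
#' remain zero by convention.
#'
#' Multiple sinogram frames may be reconstructed in one call (one
#' column per frame); the update is applied to all columns jointly.
#'
#' @param p Sinogram counts, vector or bins x frames matrix, >= 0.
#' @param system A `pet_system`.
#' @param r Background (randoms + scatter) means, same shape as `p`
#'   (scalar recycled). Default 0.
#' @param n_iter Number of EM iterations (default 100).
#' @param x0 Initial image, vector or pixels x frames matrix; default 1
#'   inside the field-of-view disk, 0 outside.
#' @param eps Clamp for denominators (default 1e-12).
#' @return Reconstructed image, same column structure as `p`.
#' @export
mlem <- function(p, system, r = 0, n_iter = 100L, x0 = NULL, eps = 1e-12) {
  P <- as.matrix(p)
  if (nrow(P) != nrow(system$H))
    stop("sinogram length does not match the system geometry")
  if (any(P < 0)) stop("sinogram counts must be nonnegative")
  R <- if (length(r) == 1L) matrix(r, nrow(P), ncol(P)) else as.matrix(r)
  if (any(R < 0)) stop("background means must be nonnegative")
  if (!all(dim(R) == dim(P))) stop("background must match the sinogram shape")

  if (all(P == 0) && all(R == 0)) {
    warning("all-zero sinogram with zero background: returning a zero image")
    out <- matrix(0, ncol(system$H), ncol(P))
    return(if (is.null(dim(p)) || ncol(P) == 1L) drop(out) else out)
  }

  X <- if (is.null(x0)) {
    matrix(as.numeric(system$fov), ncol(system$H), ncol(P))
  } else {
    x0m <- as.matrix(x0)
    if (nrow(x0m) != ncol(system$H)) stop("'x0' does not match the image size")
    if (ncol(x0m) == 1L) matrix(x0m, ncol(system$H), ncol(P)) else x0m
  }
  s <- pmax(system$sens, eps)
  H <- system$H
  for (t in seq_len(n_iter)) {
    Ybar <- as.matrix(H %*% X) + R
    ratio <- P / pmax(Ybar, eps)
    X <- X * as.matrix(Matrix::crossprod(H, ratio)) / s
  }
  X[system$sens == 0, ] <- 0
  if (is.null(dim(p)) || ncol(P) == 1L) drop(X) else X
}

#' Poisson log-likelihood of a sinogram under an image estimate
#'
#' `sum_i p_i log(ybar_i) - ybar_i` with `ybar = H x + r`, dropping the
#' data-only factorial constant. Bins with `ybar = 0` contribute 0 when
#' `p = 0` and `-Inf` otherwise.
#'
#' @inheritParams mlem
#' @param x Image estimate (vector or matrix conformable with `p`).
#' @return Scalar log-likelihood (summed over all bins and columns).
#' @export
poisson_loglik <- function(p, system, x, r = 0) {
  P <- as.matrix(p)
  X <- as.matrix(x)
  R <- if (length(r) == 1L) matrix(r, nrow(P), ncol(P)) else as.matrix(r)
  Ybar <- as.matrix(system$H %*% X) + R
  ll <- -Ybar
  pos <- P > 0
  ll[pos] <- ll[pos] + P[pos] * log(pmax(Ybar[pos], .Machine$double.xmin))
  sum(ll)
}
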