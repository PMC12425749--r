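#' Relative mean squared error
#'
#' `sum((x - x_true)^2) / sum(x_true^2)`, optionally as a percentage.
#'
#' @param x Estimate (any numeric array).
#' @param x_true Ground truth, same shape, not all zero.
#' @param percent Return the value x 100.
#' @return Scalar relative MSE.
#' @export
pet_mse <- function(x, x_true, percent = FALSE) {
  if (length(x) != length(x_true)) stop("shape mismatch")
  denom <- sum(x_true^2)
  if (denom == 0) stop("ground truth has zero norm")
  out <- sum((x - x_true)^2) / denom
  if (percent) 100 * out else out
}

#' Ensemble bias and variance over noisy realizations
#'
#' Over O realizations `x^1..x^O` of the same reconstruction:
#' `Bias = sum_j(mean_i x_j^i - x_j^true) / sum_j x_j^true` and
#' `Var = (1/O) sum_i sum_j (x_j^i - mean_i x_j^i)^2 / sum_j (x_j^true)^2`.
#'
#' @param realizations List of equally shaped numeric arrays (O >= 1).
#' @param x_true Ground truth.
#' @return List with `bias` and `var` (both scalars; `var` is 0 by
#'   construction for O = 1).
#' @export
pet_bias_variance <- function(realizations, x_true) {
  if (!is.list(realizations) || length(realizations) < 1L)
    stop("'realizations' must be a nonempty list")
  O <- length(realizations)
  if (any(vapply(realizations, length, integer(1)) != length(x_true)))
    stop("shape mismatch between realizations and ground truth")
  xbar <- Reduce(`+`, realizations) / O
  bias <- sum(xbar - x_true) / sum(x_true)
  v <- sum(vapply(realizations, function(xi) sum((xi - xbar)^2),
                  numeric(1))) / O / sum(x_true^2)
  list(bias = bias, var = v)
}

#' Mean absolute error, optionally over a region mask
#'
#' `mean(|x - x_true|)` over all pixels or over the pixels selected by
#' `mask`.
#'
#' @param x Estimate.
#' @param x_true Ground truth, same shape.
#' @param mask Optional logical mask (nonempty).
#' @return Scalar MAE.
#' @export
pet_mae <- function(x, x_true, mask = NULL) {
  if (length(x) != length(x_true)) stop("shape mismatch")
  d <- abs(x - x_true)
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty region mask")
    d <- d[mask]
  }
  mean(d)
}

# sliding-window sums over all fully interior win x win blocks,
# via an integral image
win_sums <- function(M, win) {
  n1 <- nrow(M); n2 <- ncol(M)
  S <- apply(apply(M, 2, cumsum), 1, cumsum)          # S[j, i] transposed
  S <- t(S)
  Sp <- matrix(0, n1 + 1, n2 + 1)
  Sp[2:(n1 + 1), 2:(n2 + 1)] <- S
  i <- seq_len(n1 - win + 1L); j <- seq_len(n2 - win + 1L)
  Sp[i + win, j + win, drop = FALSE] - Sp[i, j + win, drop = FALSE] -
    Sp[i + win, j, drop = FALSE] + Sp[i, j, drop = FALSE]
}

#' Structural similarity index (mean local SSIM)
#'
#' Windowed SSIM with uniform square windows slid over every fully
#' interior position, unbiased variance/covariance normalization
#' (N/(N-1)), and stabilization constants `C1 = (K1 L)^2`,
#' `C2 = (K2 L)^2` with `L` the dynamic range of the ground truth.
#' The per-window SSIM map is averaged to a scalar.
#'
#' @param x Estimate, matrix.
#' @param x_true Ground truth, matrix of the same shape.
#' @param win Window side in pixels (default 8).
#' @param L Dynamic range; default `max(x_true) - min(x_true)` (1 is
#'   used if the truth is constant).
#' @param K Stabilization multipliers `c(K1, K2)` (default 0.01, 0.03).
#' @return Scalar mean SSIM in [-1, 1].
#' @export
pet_ssim <- function(x, x_true, win = 8L, L = NULL, K = c(0.01, 0.03)) {
  x <- as.matrix(x); x_true <- as.matrix(x_true)
  if (!all(dim(x) == dim(x_true))) stop("shape mismatch")
  if (any(dim(x) < win)) stop("image smaller than the SSIM window")
  if (is.null(L)) L <- diff(range(x_true))
  if (L <= 0) L <- 1
  C1 <- (K[1] * L)^2; C2 <- (K[2] * L)^2
  NP <- win^2
  norm <- NP / (NP - 1)
  ux <- win_sums(x, win) / NP
  uy <- win_sums(x_true, win) / NP
  vx <- norm * (win_sums(x^2, win) / NP - ux^2)
  vy <- norm * (win_sums(x_true^2, win) / NP - uy^2)
  cxy <- norm * (win_sums(x * x_true, win) / NP - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Contrast-to-noise summary for rectangular boxes
#'
#' Reporting utility for contrast-noise trade-off curves: the mean
#' over a rectangular region of interest and the standard deviation
#' over a background box normalized by the background mean.
#'
#' @param image Image matrix.
#' @param roi_box,bg_box Integer vectors `c(row0, row1, col0, col1)`
#'   (inclusive).
#' @return List with `roi_mean`, `bg_sd`, `bg_mean`,
#'   `noise` (= bg_sd / bg_mean).
#' @export
contrast_noise <- function(image, roi_box, bg_box) {
  gb <- function(b) image[b[1]:b[2], b[3]:b[4]]
  roi <- gb(roi_box); bg <- gb(bg_box)
  list(roi_mean = mean(roi), bg_sd = stats::sd(as.vector(bg)),
       bg_mean = mean(bg), noise = stats::sd(as.vector(bg)) / mean(bg))
}

#' Evaluate reconstructions against the ground truth
#'
#' Computes the evaluation suite over one or more noisy-realization
#' reconstructions: per-frame relative MSE and SSIM (averaged over
#' realizations), ensemble bias and variance per frame, and per-region
#' MAE computed per frame then averaged over frames and realizations.
#'
#' @param recons List over realizations of pixels x frames matrices
#'   (a single matrix is accepted).
#' @param truth Ground-truth pixels x frames matrix (same scale as the
#'   reconstructions).
#' @param phantom A `pet_phantom` providing region masks (optional;
#'   region MAE is skipped when absent).
#' @return Object of class `pet_metrics`: list with `per_frame`
#'   (data.frame: frame, mse, ssim, bias, var), `summary` (means over
#'   frames), `region_mae` (named vector), `n_realizations`.
#' @export
evaluate_recon <- function(recons, truth, phantom = NULL) {
  if (!is.list(recons)) recons <- list(recons)
  O <- length(recons)
  nf <- ncol(truth)
  side <- as.integer(round(sqrt(nrow(truth))))
  mse_f <- ssim_f <- bias_f <- var_f <- numeric(nf)
  for (f in seq_len(nf)) {
    tr <- truth[, f]
    mse_f[f] <- mean(vapply(recons, function(R) pet_mse(R[, f], tr), numeric(1)))
    ssim_f[f] <- mean(vapply(recons, function(R) {
      pet_ssim(matrix(R[, f], side, side), matrix(tr, side, side))
    }, numeric(1)))
    bv <- pet_bias_variance(lapply(recons, function(R) R[, f]), tr)
    bias_f[f] <- bv$bias; var_f[f] <- bv$var
  }
  region_mae <- NULL
  if (!is.null(phantom)) {
    masks <- region_masks(phantom)
    region_mae <- vapply(masks, function(m) {
      mean(vapply(recons, function(R) {
        mean(vapply(seq_len(nf), function(f) pet_mae(R[, f], truth[, f], m),
                    numeric(1)))
      }, numeric(1)))
    }, numeric(1))
  }
  structure(list(
    per_frame = data.frame(frame = seq_len(nf), mse = mse_f, ssim = ssim_f,
                           bias = bias_f, var = var_f),
    summary = list(mse = mean(mse_f), ssim = mean(ssim_f),
                   bias = mean(bias_f), var = mean(var_f)),
    region_mae = region_mae, n_realizations = O
  ), class = "pet_metrics")
}

#' @export
print.pet_metrics <- function(x, ...) {
  cat(sprintf("Reconstruction metrics over %d realization(s), %d frame(s)\n",
              x$n_realizations, nrow(x$per_frame)))
  cat(sprintf("  mean MSE %.4g (%.3g%%), mean SSIM %.4f, bias %.4g, var %.4g\n",
              x$summary$mse, 100 * x$summary$mse, x$summary$ssim,
              x$summary$bias, x$summary$var))
  if (!is.null(x$region_mae)) {
    cat("  per-region MAE (frame-averaged):\n")
    print(round(x$region_mae, 4))
  }
  invisible(x)
}
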