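#' Smooth a sinogram frame with a 3 x 3 Gaussian kernel
#'
#' Fixed 3 x 3 Gaussian (sigma = 0.85 px by default), normalized to sum
#' one, applied with reflected (edge-replicating) borders.
#'
#' @param frame Numeric matrix (n_angles x n_radial).
#' @param sigma Kernel standard deviation in pixels.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_frame <- function(frame, sigma = 0.85) {
  k1 <- exp(-(-1:1)^2 / (2 * sigma^2))
  ker <- outer(k1, k1)
  ker <- ker / sum(ker)
  nr <- nrow(frame); nc <- ncol(frame)
  # reflect-pad by one pixel (edge replication)
  pr <- frame[c(1, seq_len(nr), nr), , drop = FALSE]
  pp <- pr[, c(1, seq_len(nc), nc), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out + ker[dr + 2, dc + 2] *
      pp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

#' Default composite-frame grouping
#'
#' For the standard 24-frame schedule the groups are frames 1-8, 9-16,
#' 17-20 and 21-24; for other frame counts, four contiguous groups of
#' near-equal size.
#'
#' @param n_frames Number of dynamic frames.
#' @return List of integer index vectors.
#' @export
default_grouping <- function(n_frames) {
  if (n_frames == 24L) {
    list(1:8, 9:16, 17:20, 21:24)
  } else {
    g <- min(4L, n_frames)
    split(seq_len(n_frames), cut(seq_len(n_frames), g, labels = FALSE))
  }
}

#' Fuse adjacent frames into composite frames
#'
#' Each composite column is a convex combination
#' `Z_g = sum_{l in N(g)} alpha_l Y_l` of the frames in its group; the
#' weights default to the frame durations within the group (count-
#' weighted fusion, matched to Poisson statistics) and are normalized
#' to sum one. Each composite column is then divided by its standard
#' deviation so that the spatial similarity kernel sees
#' scale-balanced features.
#'
#' @param Y Sinogram sequence, bins x frames, >= 0.
#' @param grouping List of frame-index vectors (subsets of 1..F).
#' @param weights List of per-group weight vectors (auto-normalized),
#'   or `NULL` for duration weights from `durations` (uniform if that
#'   is `NULL` too).
#' @param durations Optional per-frame durations used to derive
#'   default weights.
#' @param normalize Divide each composite column by its standard
#'   deviation (default TRUE).
#' @return List of class `composite_frames`: `Z` (bins x G), `Z_raw`
#'   (before normalization), `grouping`, `weights`, `sd` (per-column
#'   normalizers).
#' @export
make_composite_frames <- function(Y, grouping = default_grouping(ncol(Y)),
                                  weights = NULL, durations = NULL,
                                  normalize = TRUE) {
  Y <- as.matrix(Y)
  if (any(vapply(grouping, length, integer(1)) == 0L))
    stop("empty composite-frame group")
  if (any(unlist(grouping) < 1L) || any(unlist(grouping) > ncol(Y)))
    stop("grouping indexes frames outside 1..", ncol(Y))
  if (is.null(weights)) {
    weights <- lapply(grouping, function(g) {
      if (is.null(durations)) rep(1, length(g)) else durations[g]
    })
  }
  weights <- Map(function(w, g) {
    if (length(w) != length(g)) stop("weight/group length mismatch")
    w / sum(w)
  }, weights, grouping)
  Z_raw <- vapply(seq_along(grouping), function(gi) {
    as.vector(Y[, grouping[[gi]], drop = FALSE] %*% weights[[gi]])
  }, numeric(nrow(Y)))
  Z_raw <- matrix(Z_raw, nrow(Y), length(grouping))
  sds <- apply(Z_raw, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- if (normalize) sweep(Z_raw, 2, sds, "/") else Z_raw
  structure(list(Z = Z, Z_raw = Z_raw, grouping = grouping,
                 weights = weights, sd = sds),
            class = "composite_frames")
}

#' Append local patch context to composite-frame features
#'
#' Optional feature augmentation for the spatial graph: each bin's
#' feature vector is extended with the values of its square
#' neighbourhood (radius `patch_radius`, reflected borders) in every
#' composite frame.
#'
#' @param Z Bins x G feature matrix (column-major over an
#'   n_angles x n_radial grid).
#' @param n_angles,n_radial Sinogram geometry.
#' @param patch_radius Neighbourhood radius in bins (0 = no context).
#' @return Bins x (G * (2*patch_radius+1)^2) feature matrix.
#' @export
patch_features <- function(Z, n_angles, n_radial, patch_radius = 1L) {
  if (patch_radius < 1L) return(Z)
  shifts <- expand.grid(dr = -patch_radius:patch_radius,
                        dc = -patch_radius:patch_radius)
  cols <- vector("list", nrow(shifts) * ncol(Z))
  ci <- 0L
  for (g in seq_len(ncol(Z))) {
    M <- matrix(Z[, g], n_angles, n_radial)
    for (s in seq_len(nrow(shifts))) {
      ri <- pmin(pmax(seq_len(n_angles) + shifts$dr[s], 1L), n_angles)
      cj <- pmin(pmax(seq_len(n_radial) + shifts$dc[s], 1L), n_radial)
      ci <- ci + 1L
      cols[[ci]] <- as.vector(M[ri, cj])
    }
  }
  do.call(cbind, cols)
}

# exact k nearest neighbours (excluding self) by squared Euclidean
# distance, computed in row chunks; ties broken by lower node index
knn_search <- function(X, k, chunk = 1024L) {
  n <- nrow(X)
  if (k >= n) stop("'k' must be smaller than the number of nodes")
  rs <- rowSums(X^2)
  nb_idx <- matrix(0L, n, k)
  nb_d2 <- matrix(0, n, k)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    D2 <- outer(rs[rows], rs, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    D2[cbind(seq_along(rows), rows)] <- Inf  # exclude self
    D2[D2 < 0] <- 0
    for (ri in seq_along(rows)) {
      d <- D2[ri, ]
      ord <- order(d, seq_len(n))[seq_len(k)]
      nb_idx[rows[ri], ] <- ord
      nb_d2[rows[ri], ] <- d[ord]
    }
  }
  list(index = nb_idx, dist2 = nb_d2)
}

#' Build the spatial k-nearest-neighbour graph filter
#'
#' Nodes are sinogram bins; the feature vector of bin m is its row of
#' the composite-frame matrix (optionally with patch context). The k
#' nearest neighbours by Euclidean distance are retained and weighted
#' with a Gaussian kernel `w_mn = exp(-||Z_m - Z_n||^2 / (s0 sigma_s^2))`.
#' With `scale = "auto"` (the default) `s0` is the mean retained
#' kNN squared distance, so `sigma_s` is a dimensionless sensitivity
#' relative to the typical neighbour similarity and transfers across
#' geometries and iteration stages; with `scale = "none"` the plain
#' kernel `exp(-||.||^2 / sigma_s^2)` is used. The graph is symmetrized
#' by elementwise maximum (the kernel is symmetric, so this is the
#' union of the directed kNN edges), and unit self-loops are added
#' before symmetric normalization.
#'
#' @param Z Bins x G feature matrix, or a `composite_frames` object.
#' @param k Number of neighbours (default 80).
#' @param sigma_s Gaussian kernel scale (default 0.5).
#' @param scale Kernel distance normalization, `"auto"` (self-tuning)
#'   or `"none"` (absolute distances).
#' @return A `graph_filter` (see [normalize_filter()]).
#' @export
spatial_knn_graph <- function(Z, k = 80L, sigma_s = 0.5,
                              scale = c("auto", "none")) {
  scale <- match.arg(scale)
  if (inherits(Z, "composite_frames")) Z <- Z$Z
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (k >= n) stop("'k' must be smaller than the number of nodes (bins)")
  if (sigma_s <= 0) stop("'sigma_s' must be positive")
  nn <- knn_search(Z, k)
  s0 <- if (scale == "auto") mean(nn$dist2) else 1
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn$index))
  w <- exp(-as.vector(t(nn$dist2)) / s0 / sigma_s^2)
  # union symmetrization: both directions carry the same kernel weight
  ii <- c(i, j, seq_len(n))
  jj <- c(j, i, seq_len(n))
  ww <- c(w, w, rep(1, n))
  key <- (as.numeric(ii) - 1) * n + as.numeric(jj)
  keep <- !duplicated(key)
  W <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = ww[keep],
                            dims = c(n, n))
  normalize_filter(W, sigma = sigma_s)
}

#' High-activity bin mask for the temporal graph
#'
#' Each frame is pre-smoothed with the 3 x 3 Gaussian kernel, the
#' smoothed frames are summed over time, and the mask keeps bins whose
#' summed value exceeds `tau` times the maximum of that sum, so the
#' temporal similarity is driven by tracer kinetics rather than by
#' low-count background bins.
#'
#' @param Y Sinogram sequence, bins x frames.
#' @param n_angles,n_radial Sinogram geometry.
#' @param tau Relative threshold in (0, 1), default 0.1.
#' @return Logical vector over bins. An empty mask falls back to
#'   all bins with a warning.
#' @export
temporal_mask <- function(Y, n_angles, n_radial, tau = 0.1) {
  if (tau <= 0 || tau >= 1) stop("'tau' must be in (0, 1)")
  Y <- as.matrix(Y)
  tot <- rowSums(vapply(seq_len(ncol(Y)), function(f) {
    as.vector(smooth_frame(matrix(Y[, f], n_angles, n_radial)))
  }, numeric(nrow(Y))))
  mask <- tot > tau * max(tot)
  if (!any(mask)) {
    warning("empty high-activity mask; falling back to all bins")
    mask <- rep(TRUE, length(mask))
  }
  mask
}

#' Build the temporal graph filter over dynamic frames
#'
#' Nodes are the F time frames. Each frame is pre-smoothed with the
#' 3 x 3 Gaussian kernel and restricted to the high-activity mask; the
#' adjacency is `w_pq = exp(-d2(Y_p, Y_q) / (s0 sigma_t^2))` for frames
#' within the temporal window (`|p - q| <= (window - 1)/2`, truncated
#' at the sequence ends) and zero otherwise, with unit self-loops.
#' Distances are amplitude-sensitive (frames are *not* rescaled
#' individually), so frames are only pooled when their masked activity
#' profiles genuinely agree. With `scale = "auto"` (the default) `d2`
#' is the mean squared difference over in-mask bins and `s0` is the
#' lower decile of the in-window distances — a robust scale of the
#' "genuinely similar" pair population, since a fixed window always
#' contains dissimilar kinetic phases as well; with `scale = "none"`
#' the plain kernel on the summed squared difference is used.
#'
#' @param Y Sinogram sequence, bins x frames.
#' @param n_angles,n_radial Sinogram geometry.
#' @param window Odd temporal window size (default 9).
#' @param sigma_t Gaussian kernel scale (default 1).
#' @param mask Logical bin mask; default computed by
#'   [temporal_mask()].
#' @param tau Mask threshold when `mask` is NULL.
#' @param scale Kernel distance normalization, `"auto"` (self-tuning)
#'   or `"none"` (absolute distances).
#' @return A `graph_filter` over the F frames.
#' @export
temporal_graph <- function(Y, n_angles, n_radial, window = 9L, sigma_t = 1,
                           mask = NULL, tau = 0.1,
                           scale = c("auto", "none")) {
  scale <- match.arg(scale)
  Y <- as.matrix(Y)
  if (window < 1L) stop("'window' must be >= 1")
  if (window %% 2L == 0L) stop("'window' must be odd")
  if (sigma_t <= 0) stop("'sigma_t' must be positive")
  F_ <- ncol(Y)
  S <- vapply(seq_len(F_), function(f) {
    as.vector(smooth_frame(matrix(Y[, f], n_angles, n_radial)))
  }, numeric(nrow(Y)))
  if (is.null(mask)) mask <- temporal_mask(Y, n_angles, n_radial, tau)
  V <- S[mask, , drop = FALSE]
  half <- (window - 1L) %/% 2L
  ii <- integer(0); jj <- integer(0); dd <- numeric(0)
  for (p in seq_len(F_)) {
    qs <- setdiff(max(1L, p - half):min(F_, p + half), p)
    if (!length(qs)) next
    dv <- (V[, qs, drop = FALSE] - V[, p])^2
    d2 <- if (scale == "auto") colMeans(dv) else colSums(dv)
    ii <- c(ii, rep(p, length(qs))); jj <- c(jj, qs)
    dd <- c(dd, d2)
  }
  s0 <- if (scale == "auto" && length(dd)) {
    as.numeric(stats::quantile(dd, 0.10))
  } else 1
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  ww <- exp(-dd / s0 / sigma_t^2)
  W <- Matrix::sparseMatrix(i = c(ii, seq_len(F_)), j = c(jj, seq_len(F_)),
                            x = c(ww, rep(1, F_)), dims = c(F_, F_))
  normalize_filter(W, sigma = sigma_t)
}

#' Symmetrically normalize an adjacency matrix into a graph filter
#'
#' Computes `F = D^{-1/2} W D^{-1/2}` with `D = diag(rowSums(W))`. For
#' a symmetric nonnegative `W` the filter is symmetric, its spectrum
#' lies in [-1, 1], and `D^{1/2} 1` is an eigenvector with eigenvalue 1
#' on each connected component, so the filter acts as a non-expansive
#' graph low-pass operator.
#'
#' @param W Symmetric nonnegative (sparse or dense) adjacency matrix
#'   with strictly positive degrees (guaranteed when self-loops are
#'   present).
#' @param sigma Optional kernel scale recorded for provenance.
#' @return Object of class `graph_filter`: list with `W`, `degree`,
#'   `F` (sparse), `n`, `sigma`.
#' @export
normalize_filter <- function(W, sigma = NA_real_) {
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  if (nrow(W) != ncol(W)) stop("'W' must be square")
  if (any(W@x < 0)) stop("'W' must be nonnegative")
  if (max(abs(W - Matrix::t(W))) > 1e-10) stop("'W' must be symmetric")
  d <- as.numeric(Matrix::rowSums(W))
  if (any(d <= 0)) stop("zero-degree node: add self-loops before normalizing")
  Dm <- Matrix::Diagonal(x = 1 / sqrt(d))
  Fm <- Dm %*% W %*% Dm
  structure(list(W = W, degree = d, F = Fm, n = nrow(W), sigma = sigma),
            class = "graph_filter")
}

#' @export
print.graph_filter <- function(x, ...) {
  cat(sprintf("Graph filter: %d nodes, %d edges (incl. self-loops), sigma = %s\n",
              x$n, length(x$W@x), format(x$sigma)))
  invisible(x)
}

#' Export a graph filter as plain-text sparse matrices with a JSON sidecar
#'
#' Writes `<prefix>_W.mtx` and `<prefix>_F.mtx` (MatrixMarket
#' coordinate format) and `<prefix>.json` with node count, kernel
#' scale and degree summary.
#'
#' @param gf A `graph_filter`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
export_graph <- function(gf, prefix) {
  stopifnot(inherits(gf, "graph_filter"))
  pw <- paste0(prefix, "_W.mtx"); pf <- paste0(prefix, "_F.mtx")
  pj <- paste0(prefix, ".json")
  Matrix::writeMM(gf$W, pw)
  Matrix::writeMM(methods::as(gf$F, "generalMatrix"), pf)
  jsonlite::write_json(list(nodes = gf$n, sigma = gf$sigma,
                            edges = length(gf$W@x),
                            degree = list(min = min(gf$degree),
                                          max = max(gf$degree),
                                          mean = mean(gf$degree))),
                       pj, auto_unbox = TRUE, digits = NA)
  invisible(c(pw, pf, pj))
}
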