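#' Build a sparse line-integral system matrix
#'
#' Siddon-style exact pixel-intersection-length projector on a uniform
#' parallel-beam geometry: `n_angles` view angles uniformly spaced on
#' [0, pi) and `n_radial` unit-spaced radial bins centred on the image.
#' Pixels are unit squares on `[-side/2, side/2]^2`; the weight of
#' pixel j in sinogram bin i is the length of ray i inside pixel j.
#' Backprojection is the exact transpose.
#'
#' @param image_side Image side in pixels.
#' @param n_angles Number of projection angles (default `image_side`).
#' @param n_radial Number of radial bins (default `image_side`).
#' @return Object of class `pet_system`: list with sparse `H`
#'   (n_angles*n_radial x image_side^2, bins ordered radial-fastest),
#'   `sens` = t(H) %*% 1, `fov` logical in-field-of-view pixel mask,
#'   and the geometry.
#' @export
build_system_matrix <- function(image_side, n_angles = image_side,
                                n_radial = image_side) {
  image_side <- as.integer(image_side)
  n_angles <- as.integer(n_angles)
  n_radial <- as.integer(n_radial)
  if (image_side < 1L || n_angles < 1L || n_radial < 1L)
    stop("degenerate geometry: all dimensions must be >= 1")

  n <- image_side
  half <- n / 2
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles
  offsets <- seq_len(n_radial) - (n_radial + 1) / 2
  # grid lines at integer coordinates -half, ..., half
  glines <- -half + 0:n

  ii <- vector("list", n_angles * n_radial)
  jj <- vector("list", n_angles * n_radial)
  xx <- vector("list", n_angles * n_radial)
  ray <- 0L
  for (a in seq_len(n_angles)) {
    ct <- cos(angles[a]); st <- sin(angles[a])
    # ray: p(tau) = t*(ct, st) + tau*(-st, ct)
    for (k in seq_len(n_radial)) {
      ray <- ray + 1L
      t0 <- offsets[k]
      px <- t0 * ct; py <- t0 * st
      taus <- numeric(0)
      if (abs(st) > 1e-12) taus <- c(taus, (px - glines) / st)   # x crossings
      if (abs(ct) > 1e-12) taus <- c(taus, (glines - py) / ct)   # y crossings
      if (!length(taus)) next
      # clip to the bounding box
      tx <- if (abs(st) > 1e-12) range((px - c(-half, half)) / st) else c(-Inf, Inf)
      ty <- if (abs(ct) > 1e-12) range((c(-half, half) - py) / ct) else c(-Inf, Inf)
      lo <- max(tx[1], ty[1]); hi <- min(tx[2], ty[2])
      if (hi <= lo) next
      taus <- sort(unique(c(lo, taus[taus > lo & taus < hi], hi)))
      if (length(taus) < 2L) next
      len <- diff(taus)
      tm <- (taus[-1] + taus[-length(taus)]) / 2
      xm <- px - tm * st
      ym <- py + tm * ct
      col <- floor(xm + half) + 1
      row <- floor(half - ym) + 1
      ok <- len > 1e-12 & col >= 1 & col <= n & row >= 1 & row <= n
      if (!any(ok)) next
      ii[[ray]] <- rep.int(ray, sum(ok))
      jj[[ray]] <- (col[ok] - 1L) * n + row[ok]   # column-major pixel index
      xx[[ray]] <- len[ok]
    }
  }
  H <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_angles * n_radial, n * n))
  sens <- as.numeric(Matrix::crossprod(H, rep(1, nrow(H))))
  cx <- (matrix(seq_len(n), n, n, byrow = TRUE) - (n + 1) / 2)
  cy <- (matrix(seq_len(n), n, n) - (n + 1) / 2)
  fov <- as.vector(cx^2 + cy^2 <= half^2) & sens > 0
  structure(list(H = H, sens = sens, fov = fov,
                 image_side = n, n_angles = n_angles, n_radial = n_radial),
            class = "pet_system")
}

#' @export
print.pet_system <- function(x, ...) {
  cat(sprintf("PET system model: %d angles x %d radial bins -> %d x %d image (%d nonzeros)\n",
              x$n_angles, x$n_radial, x$image_side, x$image_side,
              length(x$H@x)))
  invisible(x)
}

#' Forward-project an image to a sinogram
#'
#' @param system A `pet_system`.
#' @param image Numeric vector of length side^2 (column-major) or a
#'   matrix with one image per column.
#' @return Sinogram vector (or matrix, one column per input column).
#' @export
forward_project <- function(system, image) {
  img <- as.matrix(image)
  if (nrow(img) != ncol(system$H))
    stop("image length does not match the system geometry")
  out <- as.matrix(system$H %*% img)
  if (is.null(dim(image)) || ncol(img) == 1L) drop(out) else out
}

#' Backproject a sinogram to image space (exact transpose of forward)
#'
#' @param system A `pet_system`.
#' @param sinogram Numeric vector of length n_angles*n_radial or matrix
#'   with one sinogram per column.
#' @return Image vector (or matrix).
#' @export
back_project <- function(system, sinogram) {
  sg <- as.matrix(sinogram)
  if (nrow(sg) != nrow(system$H))
    stop("sinogram length does not match the system geometry")
  out <- as.matrix(Matrix::crossprod(system$H, sg))
  if (is.null(dim(sinogram)) || ncol(sg) == 1L) drop(out) else out
}
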