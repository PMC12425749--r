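# Independent brute-force ray tracer: for a parallel-beam ray with angle
# theta and radial offset t, the length inside each unit pixel square is
# computed by Liang-Barsky interval clipping, pixel by pixel. Used as an
# oracle for the sparse Siddon-style projector; shares no code with it.
bf_ray_lengths <- function(n, theta, t_off) {
  half <- n / 2
  ct <- cos(theta); st <- sin(theta)
  # pixel (row, col): x in [xl, xl+1], y in [yt-1, yt]
  col <- rep(seq_len(n), each = n)
  row <- rep(seq_len(n), times = n)
  xl <- -half + col - 1; xr <- xl + 1
  yt <- half - row + 1; yb <- yt - 1
  # ray: x(tau) = t*ct - tau*st ; y(tau) = t*st + tau*ct
  lo <- rep(-Inf, n * n); hi <- rep(Inf, n * n)
  if (abs(st) > 1e-14) {
    t1 <- (t_off * ct - xl) / st; t2 <- (t_off * ct - xr) / st
    lo <- pmax(lo, pmin(t1, t2)); hi <- pmin(hi, pmax(t1, t2))
  } else if (any(t_off * ct < xl | t_off * ct > xr)) {
    out <- t_off * ct < xl | t_off * ct > xr
    hi[out] <- -Inf
  }
  if (abs(ct) > 1e-14) {
    t1 <- (yb - t_off * st) / ct; t2 <- (yt - t_off * st) / ct
    lo <- pmax(lo, pmin(t1, t2)); hi <- pmin(hi, pmax(t1, t2))
  } else {
    out <- t_off * st < yb | t_off * st > yt
    hi[out] <- -Inf
  }
  pmax(hi - lo, 0)  # column-major pixel order: index = (col-1)*n + row
}

bf_forward <- function(image_vec, n, n_angles, n_radial) {
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  offsets <- seq_len(n_radial) - (n_radial + 1) / 2
  out <- numeric(n_angles * n_radial)
  ray <- 0L
  for (a in angles) for (t0 in offsets) {
    ray <- ray + 1L
    out[ray] <- sum(bf_ray_lengths(n, a, t0) * image_vec)
  }
  out
}

# brute-force exhaustive kNN by full pairwise squared distances
bf_knn <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  diag(D) <- Inf
  t(vapply(seq_len(n), function(i) order(D[i, ], seq_len(n))[seq_len(k)],
           integer(k)))
}

# small seeded dataset shared across engine tests (built once per run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        ds = simulate_dataset(phantom = make_phantom(31L, 3L),
                              n_realizations = 2L, seed = 42L),
        sys = build_system_matrix(31L)
      )
    }
    cache
  }
})

# random symmetric nonnegative adjacency with unit self-loops
random_adjacency <- function(n, density = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  m <- ceiling(density * n * (n - 1) / 2)
  idx <- which(upper.tri(A))
  pick <- sample(idx, m)
  A[pick] <- runif(m)
  A <- A + t(A)
  diag(A) <- 1
  A
}
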