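test_that("composite frames fuse groups with normalized weights", {
  set.seed(2)
  Y <- matrix(rpois(40 * 24, 30), 40, 24)
  cf <- make_composite_frames(Y)
  expect_equal(ncol(cf$Z), 4L)
  expect_equal(cf$grouping, list(1:8, 9:16, 17:20, 21:24))
  for (w in cf$weights) expect_equal(sum(w), 1)
  # single all-frame group with uniform weights is the framewise mean
  cf2 <- make_composite_frames(Y, grouping = list(1:24), normalize = FALSE)
  expect_equal(as.vector(cf2$Z), rowMeans(Y))
  # constant input stays constant before normalization (convexity)
  Yc <- matrix(7, 40, 24)
  cf3 <- make_composite_frames(Yc, normalize = FALSE)
  expect_true(all(abs(cf3$Z - 7) < 1e-12))
  expect_error(make_composite_frames(Y, grouping = list(integer(0))), "empty")
  # duration weighting: group value is the count-weighted rate fusion
  dur <- c(rep(20, 8), rep(40, 8), rep(60, 8))
  cfd <- make_composite_frames(Y[, 1:24], grouping = list(1:8),
                               durations = dur, normalize = FALSE)
  expect_equal(as.vector(cfd$Z),
               as.vector(Y[, 1:8] %*% (dur[1:8] / sum(dur[1:8]))))
})

test_that("spatial kNN graph matches the exhaustive neighbour oracle", {
  # 6 scalar features: neighbour sets recovered by brute force
  Z <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  gf <- spatial_knn_graph(Z, k = 2, sigma_s = 0.5, scale = "none")
  oracle <- bf_knn(Z, 2)
  W <- as.matrix(gf$W)
  for (i in 1:6) {
    nb <- setdiff(which(W[i, ] > 0), i)
    expect_true(all(oracle[i, ] %in% nb))
  }
  # larger random instance: retained off-diagonal support is the union
  # of directed kNN edges found by exhaustive search
  set.seed(9)
  Z2 <- matrix(runif(60), 30, 2)
  k <- 4
  gf2 <- spatial_knn_graph(Z2, k = k, sigma_s = 1, scale = "none")
  o2 <- bf_knn(Z2, k)
  A <- matrix(FALSE, 30, 30)
  for (i in 1:30) A[i, o2[i, ]] <- TRUE
  A <- A | t(A); diag(A) <- TRUE
  expect_equal(as.matrix(gf2$W) > 0, A, ignore_attr = TRUE)
})

test_that("spatial kernel weights take the analytic Gaussian values", {
  # identical features: every retained weight is exp(0) = 1
  Z <- matrix(1, 10, 2)
  gf <- spatial_knn_graph(Z, k = 3, sigma_s = 0.5, scale = "none")
  expect_true(all(abs(gf$W@x - 1) < 1e-12))
  # squared distance equal to sigma^2 gives weight e^{-1}
  sig <- 0.7
  Z2 <- matrix(c(0, sig, 10, 10.001), ncol = 1)
  gf2 <- spatial_knn_graph(Z2, k = 1, sigma_s = sig, scale = "none")
  expect_equal(as.numeric(gf2$W[1, 2]), exp(-1), tolerance = 1e-12)
  expect_error(spatial_knn_graph(Z2, k = 4), "smaller")
  expect_error(spatial_knn_graph(Z2, k = 1, sigma_s = 0), "positive")
})

test_that("temporal mask selects high-activity bins with smoothing halo", {
  # uniform positive input: full mask for any tau < 1
  Y <- matrix(1, 25, 3)
  expect_true(all(temporal_mask(Y, 5, 5, tau = 0.9)))
  # single hot bin: mask is the bin plus its 3x3 smoothing halo only
  Y2 <- matrix(0, 25, 2)
  Y2[13, ] <- 100  # centre of the 5x5 grid
  m <- temporal_mask(Y2, 5, 5, tau = 0.5)
  halo <- as.vector(matrix(seq_len(25), 5, 5)[2:4, 2:4])
  expect_true(all(m[13]))
  expect_true(all(which(m) %in% halo))
  # threshold monotonicity: smaller tau gives a superset
  set.seed(4)
  Y3 <- matrix(rpois(50 * 4, 8), 50, 4)
  m_lo <- temporal_mask(Y3, 10, 5, tau = 0.1)
  m_hi <- temporal_mask(Y3, 10, 5, tau = 0.6)
  expect_true(all(which(m_hi) %in% which(m_lo)))
  # an all-zero input falls back to all bins with a warning
  expect_warning(m0 <- temporal_mask(matrix(0, 25, 2), 5, 5, tau = 0.5),
                 "empty")
  expect_true(all(m0))
  expect_error(temporal_mask(Y, 5, 5, tau = 1.2), "tau")
})

test_that("temporal graph respects the window and analytic kernel values", {
  set.seed(6)
  Y <- matrix(rpois(36 * 24, 20), 36, 24)
  gf <- temporal_graph(Y, 6, 6, window = 9)
  W <- as.matrix(gf$W)
  # frame 12 can reach frames 8..16; frame 1 only 1..5
  expect_true(all(which(W[12, ] > 0) %in% 8:16))
  expect_true(all(which(W[1, ] > 0) %in% 1:5))
  expect_equal(which(W[1, ] > 0), 1:5)
  # identical frames: every in-window weight is 1
  Yc <- matrix(rep(rpois(36, 50), 24), 36, 24)
  gfc <- temporal_graph(Yc, 6, 6, window = 9)
  expect_true(all(abs(gfc$W@x - 1) < 1e-12))
  # masked squared distance sigma_t^2 gives weight e^{-1} (plain kernel):
  # constant frames passed with a full mask so smoothing changes nothing
  sig <- 2.5
  Y2 <- cbind(rep(0, 25), rep(sig / 5, 25))  # sum of squares = sig^2
  gf2 <- temporal_graph(Y2, 5, 5, window = 3, sigma_t = sig,
                        mask = rep(TRUE, 25), scale = "none")
  expect_equal(as.numeric(gf2$W[1, 2]), exp(-1), tolerance = 1e-12)
  expect_error(temporal_graph(Y, 6, 6, window = 4), "odd")
  expect_error(temporal_graph(Y, 6, 6, window = 0), "odd|>= 1")
})

test_that("symmetric normalization obeys the spectral contract", {
  # hand-checked 2x2 cases
  gf <- normalize_filter(matrix(1, 2, 2))
  expect_equal(as.matrix(gf$F), matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(as.numeric(gf$F %*% c(1, 3)), c(2, 2))
  gfi <- normalize_filter(diag(2))
  expect_equal(as.matrix(gfi$F), diag(2), ignore_attr = TRUE)
  # random graphs up to 100 nodes against the dense eigensolver
  for (n in c(8L, 40L, 100L)) {
    A <- random_adjacency(n, seed = n)
    gf <- normalize_filter(A)
    ev <- eigen(as.matrix(gf$F), symmetric = TRUE)
    expect_lte(max(ev$values), 1 + 1e-10)
    expect_gte(min(ev$values), -1 - 1e-10)
    expect_equal(max(ev$values), 1, tolerance = 1e-10)
    # top eigenvector is D^{1/2} 1 (graph is connected w.h.p. at this density)
    v <- sqrt(gf$degree); v <- v / sqrt(sum(v^2))
    expect_equal(as.numeric(gf$F %*% v), v, tolerance = 1e-10)
  }
  expect_error(normalize_filter(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(normalize_filter(matrix(c(0, 0, 0, 1), 2, 2)), "degree")
})

test_that("graph filtering is non-expansive and powers toward the top eigenvector", {
  A <- random_adjacency(30L, seed = 13)
  gf <- normalize_filter(A)
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(30)
    expect_lte(sqrt(sum((as.numeric(gf$F %*% x))^2)), sqrt(sum(x^2)) + 1e-12)
  }
  # repeated application converges to the projection on D^{1/2} 1
  ev <- eigen(as.matrix(gf$F), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  x <- abs(rnorm(30)) + 0.1
  for (t in 1:400) x <- as.numeric(gf$F %*% x)
  expect_equal(abs(sum(x * v1)) / sqrt(sum(x^2)), 1, tolerance = 1e-6)
})

test_that("graph construction is deterministic and exportable", {
  set.seed(21)
  Z <- matrix(runif(200), 50, 4)
  g1 <- spatial_knn_graph(Z, k = 5)
  g2 <- spatial_knn_graph(Z, k = 5)
  expect_identical(as.matrix(g1$W), as.matrix(g2$W))
  tmp <- tempfile()
  paths <- export_graph(g1, tmp)
  expect_true(all(file.exists(paths)))
  W_back <- Matrix::readMM(paths[1])
  expect_equal(as.matrix(W_back), as.matrix(g1$W), tolerance = 1e-12,
               ignore_attr = TRUE)
})
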