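test_that("build_graph computes components and Laplacian spectrum bounds", {
  # K2 with weight w: Laplacian eigenvalues {0, 2w}
  w <- 3.5
  G <- build_graph(matrix(c(0, w, w, 0), 2, 2))
  expect_length(G$components, 1)
  expect_equal(G$lambda_max[1], 2 * w, tolerance = 1e-10)

  # block-diagonal two cliques (no bridge) -> two components
  W <- make_two_clique(5)
  W[5, 6] <- 0; W[6, 5] <- 0
  G2 <- build_graph(W)
  expect_length(G2$components, 2)
  expect_identical(lengths(G2$components), c(`1` = 5L, `2` = 5L))

  # P4 path: eigenvalues {0, 2-sqrt(2), 2, 2+sqrt(2)}
  G3 <- build_graph(make_path(4))
  expect_equal(G3$lambda_2[1], 2 - sqrt(2), tolerance = 1e-10)
  expect_equal(G3$lambda_max[1], 2 + sqrt(2), tolerance = 1e-10)

  # the power-iteration path agrees with the dense path (inflated <= 1%)
  G4 <- build_graph(make_two_clique(10), dense_limit = 2L)
  G5 <- build_graph(make_two_clique(10))
  expect_equal(G4$lambda_2[1], G5$lambda_2[1], tolerance = 1e-3)
  expect_true(G4$lambda_max[1] >= G5$lambda_max[1])
  expect_lt(G4$lambda_max[1] / G5$lambda_max[1], 1.02)

  expect_error(build_graph(matrix(numeric(0), 0, 0)), "empty")
})

test_that("scale grid is geometric and tracks the spectrum", {
  G <- build_graph(make_two_clique(8))
  g2 <- scale_grid(G, J = 2)
  expect_equal(g2$scales, c(g2$s_min, g2$s_max))

  g <- scale_grid(G, J = 17)
  ratios <- g$scales[-1] / g$scales[-17]
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 1e-12)

  # doubling all edge weights doubles the spectrum, halving every scale
  Gd <- build_graph(2 * make_two_clique(8))
  gd <- scale_grid(Gd, J = 17)
  expect_equal(gd$scales, g$scales / 2, tolerance = 1e-8)

  # singleton component gets an empty grid
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  Gs <- build_graph(W)
  iso <- which(lengths(Gs$components) == 1L)
  expect_length(scale_grid(Gs, J = 5, component = iso)$scales, 0)
})

test_that("wavelet kernel matches its closed forms and is continuous", {
  x <- c(0.2, 0.7)
  expect_equal(wavelet_kernel(x), x^2)
  x <- c(1.1, 1.5, 1.9)
  expect_equal(wavelet_kernel(x), -5 + 11 * x - 6 * x^2 + x^3)
  x <- c(2.5, 4, 10)
  expect_equal(wavelet_kernel(x), 4 / x^2)
  eps <- 1e-9
  expect_equal(wavelet_kernel(1 - eps), wavelet_kernel(1 + eps),
               tolerance = 1e-6)
  expect_equal(wavelet_kernel(2 - eps), wavelet_kernel(2 + eps),
               tolerance = 1e-6)
})

test_that("exact correlation distance: diagonal, symmetry, automorphism", {
  G <- build_graph(make_two_clique(5))
  s <- exp(mean(log(c(scale_grid(G, 5)$s_min, scale_grid(G, 5)$s_max))))
  cd <- exact_correlation_distance(G, s)
  expect_equal(diag(cd$C), rep(1, 10))
  expect_equal(diag(cd$D), rep(0, 10))
  expect_equal(cd$C, t(cd$C))
  expect_true(all(cd$C >= -1 & cd$C <= 1))
  expect_true(all(cd$D >= 0 & cd$D <= 2))

  # the graph automorphism swapping the two cliques (i <-> i+5, reversing
  # within-clique order to map the bridge ends onto each other)
  p <- c(10:6, 5:1)
  expect_equal(cd$C[p, p], cd$C, tolerance = 1e-9)

  # nodes in different components get maximal distance
  W <- make_two_clique(4)
  W[4, 5] <- 0; W[5, 4] <- 0
  cd2 <- exact_correlation_distance(build_graph(W), s)
  expect_equal(cd2$D[1, 8], 2)
})

test_that("wavelets separate two bridged cliques at large scales and
           localise at small ones", {
  G <- build_graph(make_two_clique(5))
  grid <- scale_grid(G, J = 13)
  blk <- rep(1:2, each = 5)
  same <- outer(blk, blk, "==") & upper.tri(matrix(0, 10, 10))
  diff <- (!outer(blk, blk, "==")) & upper.tri(matrix(0, 10, 10))
  cd <- exact_correlation_distance(G, grid$scales[10])
  expect_gt(min(cd$C[same]), max(cd$C[diff]))
  # at the smallest scale wavelets are near-impulses: weak correlations
  cd0 <- exact_correlation_distance(G, grid$s_min)
  expect_lt(max(abs(cd0$C[upper.tri(cd0$C)])), 0.5)
})

test_that("fast estimator is seed-deterministic and unbiased toward the
           oracle", {
  G <- build_graph(make_two_clique(5))
  s <- exp(mean(log(c(scale_grid(G, 5)$s_min, scale_grid(G, 5)$s_max))))
  a <- fast_correlation_distance(G, s, eta = 100, seed = 9)
  b <- fast_correlation_distance(G, s, eta = 100, seed = 9)
  expect_identical(a$C, b$C)
  expect_false(identical(
    a$C, fast_correlation_distance(G, s, eta = 100, seed = 10)$C))

  ce <- exact_correlation_distance(G, s)
  reps <- lapply(1:30, function(k)
    fast_correlation_distance(G, s, eta = 200, seed = k)$C)
  Cbar <- Reduce(`+`, reps) / length(reps)
  se <- sqrt(apply(simplify2array(reps), c(1, 2), var) / length(reps))
  off <- upper.tri(Cbar)
  expect_lt(mean(abs(Cbar - ce$C)[off] > 3 * se[off] + 0.02), 0.05)
})

test_that("Chebyshev operator error decreases with polynomial order", {
  b <- generate_block_benchmark(seed = 4, n_pairs = 2)  # 100-node fixture
  G <- build_graph(b$matrix)
  grid <- scale_grid(G, 5)
  s <- exp(mean(log(c(grid$s_min, grid$s_max))))
  W <- G$weights; deg <- rowSums(W)
  L <- -W; diag(L) <- diag(L) + deg
  eg <- eigen(L, symmetric = TRUE)
  set.seed(2)
  X <- matrix(rnorm(100 * 5), 100, 5)
  exact <- eg$vectors %*% (wavelet_kernel(s * eg$values) *
                             crossprod(eg$vectors, X))
  errs <- vapply(c(10, 20, 40, 80), function(m) {
    cf <- hicwavelets:::.chebyshev_coefficients(
      function(x) wavelet_kernel(s * x), m, G$lambda_max[1])
    ap <- hicwavelets:::.chebyshev_apply(W, deg, cf, G$lambda_max[1], X)
    sqrt(sum((ap - exact)^2) / sum(exact^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 0.05)
})

test_that("far out-of-range scales trigger the Chebyshev coverage warning", {
  G <- build_graph(make_two_clique(5))
  smax <- scale_grid(G, 5)$s_max
  expect_warning(fast_correlation_distance(G, 100 * smax, eta = 10, seed = 1),
                 "Chebyshev")
  expect_error(fast_correlation_distance(G, 1, eta = 1), "eta")
})
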