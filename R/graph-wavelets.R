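# Spectral graph wavelets on the Hi-C interaction network.
#
# The contact matrix (diagonal zeroed) is the weighted adjacency W of the
# locus interaction network. Wavelets are band-pass functions g(s*L) of the
# combinatorial Laplacian L = Deg - W applied to node-localised impulses;
# the correlation between two nodes' wavelets at scale s measures the
# similarity of their neighbourhoods at that scale.

#' Build the locus interaction graph from a masked contact matrix
#'
#' The adjacency is the contact matrix with its diagonal set to zero.
#' Connected components are computed, and for each component of size >= 2
#' the Laplacian spectrum bounds needed by the wavelet construction are
#' estimated: `lambda_2` (smallest nonzero eigenvalue, the algebraic
#' connectivity) and `lambda_max` (an upper bound on the largest
#' eigenvalue). Components up to `dense_limit` nodes use a dense symmetric
#' eigendecomposition; larger ones a power iteration with the estimate
#' inflated by 1% to guarantee an upper bound.
#'
#' @param M a `ContactMatrix` (typically after [filter_loci()]) or a plain
#'   symmetric non-negative matrix.
#' @param dense_limit component size up to which dense eigendecomposition
#'   is used for the spectrum bounds.
#' @return an object of class `InteractionGraph`: `n`, `weights`,
#'   `membership` (component id per node), `components` (list of node index
#'   vectors), `lambda_2`, `lambda_max` (per component, `NA` for
#'   singletons), plus the `chrom`/`bin_size` metadata when available.
#' @export
build_graph <- function(M, dense_limit = 4096L) {
  W <- .as_values(M)
  if (length(W) == 0L) stop("empty contact matrix")
  if (nrow(W) != ncol(W)) stop("adjacency must be square")
  if (any(W < 0)) stop("adjacency must be non-negative")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  components <- split(seq_len(n), membership)
  ncomp <- length(components)
  lambda_2 <- rep(NA_real_, ncomp)
  lambda_max <- rep(NA_real_, ncomp)
  for (c in seq_len(ncomp)) {
    idx <- components[[c]]
    if (length(idx) < 2L) next
    Wc <- W[idx, idx, drop = FALSE]
    if (length(idx) <= dense_limit) {
      L <- -Wc
      diag(L) <- diag(L) + rowSums(Wc)
      ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
      lambda_max[c] <- ev[length(ev)]
      lambda_2[c] <- ev[2]
    } else {
      b <- .laplacian_bounds_iterative(Wc)
      lambda_max[c] <- b$lambda_max
      lambda_2[c] <- b$lambda_2
    }
  }
  structure(
    list(n = n, weights = W, membership = membership, components = components,
         lambda_2 = lambda_2, lambda_max = lambda_max,
         chrom = if (inherits(M, "ContactMatrix")) M$chrom else NA_character_,
         bin_size = if (inherits(M, "ContactMatrix")) M$bin_size else 1),
    class = "InteractionGraph"
  )
}

#' @export
print.InteractionGraph <- function(x, ...) {
  sizes <- lengths(x$components)
  cat(sprintf("InteractionGraph: %d nodes, %d component(s) (largest %d)\n",
              x$n, length(x$components), max(sizes)))
  invisible(x)
}

# power-iteration bounds for components too large for dense eigen:
# lambda_max from L, lambda_2 from the spectral complement lmax*I - L with
# the constant vector (the known null vector of L) projected out.
.laplacian_bounds_iterative <- function(Wc, iter = 300L, tol = 1e-10) {
  deg <- rowSums(Wc)
  nc <- nrow(Wc)
  lmv <- function(x) deg * x - as.vector(Wc %*% x)
  x <- stats::rnorm(nc); x <- x / sqrt(sum(x^2))
  lam <- 0
  for (k in seq_len(iter)) {
    y <- lmv(x)
    lam_new <- sqrt(sum(y^2))
    if (lam_new == 0) break
    x <- y / lam_new
    if (abs(lam_new - lam) < tol * lam_new && k > 10L) { lam <- lam_new; break }
    lam <- lam_new
  }
  lmax <- lam * 1.01
  one <- rep(1 / sqrt(nc), nc)
  x <- stats::rnorm(nc)
  x <- x - sum(x * one) * one
  x <- x / sqrt(sum(x^2))
  mu <- 0
  for (k in seq_len(iter)) {
    y <- lmax * x - lmv(x)
    y <- y - sum(y * one) * one
    mu_new <- sqrt(sum(y^2))
    if (mu_new == 0) break
    x <- y / mu_new
    if (abs(mu_new - mu) < tol * mu_new && k > 10L) { mu <- mu_new; break }
    mu <- mu_new
  }
  list(lambda_max = lmax, lambda_2 = max(lmax - mu, lmax * 1e-12))
}

#' Band-pass wavelet generating kernel
#'
#' The classical spectral-graph-wavelet kernel: monomial rise `(x/x1)^alpha`
#' below the pass-band, monomial decay `(x2/x)^beta` above it, and the
#' unique cubic joining them with matching values and derivatives on
#' `[x1, x2]`. With the defaults (`x1 = 1`, `x2 = 2`, `alpha = beta = 2`)
#' the cubic is `-5 + 11x - 6x^2 + x^3`.
#'
#' @param x points (>= 0) at which to evaluate.
#' @param alpha,beta monomial orders of the rise and decay.
#' @param x1,x2 pass-band limits.
#' @return kernel values.
#' @export
wavelet_kernel <- function(x, alpha = 2, beta = 2, x1 = 1, x2 = 2) {
  A <- rbind(c(1, x1, x1^2, x1^3),
             c(1, x2, x2^2, x2^3),
             c(0, 1, 2 * x1, 3 * x1^2),
             c(0, 1, 2 * x2, 3 * x2^2))
  cf <- solve(A, c(1, 1, alpha / x1, -beta / x2))
  out <- numeric(length(x))
  lo <- x < x1; hi <- x > x2; mid <- !lo & !hi
  out[lo] <- (x[lo] / x1)^alpha
  out[hi] <- (x2 / x[hi])^beta
  xm <- x[mid]
  out[mid] <- cf[1] + cf[2] * xm + cf[3] * xm^2 + cf[4] * xm^3
  out
}

# argmax of the kernel (inside the pass-band); cached for the defaults
.kernel_peak <- local({
  cache <- NULL
  function(alpha = 2, beta = 2, x1 = 1, x2 = 2) {
    default <- alpha == 2 && beta == 2 && x1 == 1 && x2 == 2
    if (default && !is.null(cache)) return(cache)
    peak <- stats::optimize(wavelet_kernel, c(x1, x2), maximum = TRUE,
                            alpha = alpha, beta = beta, x1 = x1, x2 = x2,
                            tol = 1e-10)$maximum
    if (default) cache <<- peak
    peak
  }
})

#' Logarithmic grid of wavelet scales for one component
#'
#' The scale range is tied to the component's Laplacian spectrum: at the
#' largest scale `s_max` the kernel peak response sits at `lambda_2`
#' (whole-component structures), at the smallest scale `s_min` it sits at
#' `lambda_max` (single-node structures). `J` scales are geometrically
#' spaced in between.
#'
#' @param G an `InteractionGraph`.
#' @param J number of scales (>= 2).
#' @param component component index.
#' @return an object of class `ScaleGrid`: `scales`, `s_min`, `s_max`, `J`;
#'   empty `scales` for a singleton component.
#' @export
scale_grid <- function(G, J = 100L, component = 1L) {
  J <- as.integer(J)
  if (J < 2L) stop("J must be >= 2")
  if (length(G$components[[component]]) < 2L) {
    return(structure(list(scales = numeric(0), s_min = NA_real_,
                          s_max = NA_real_, J = 0L), class = "ScaleGrid"))
  }
  peak <- .kernel_peak()
  s_min <- peak / G$lambda_max[component]
  s_max <- peak / G$lambda_2[component]
  scales <- exp(seq(log(s_min), log(s_max), length.out = J))
  structure(list(scales = scales, s_min = s_min, s_max = s_max, J = J),
            class = "ScaleGrid")
}

# Chebyshev expansion of fun on [0, lmax], coefficients c_0..c_m. The
# quadrature uses many more points than m+1 so the result is the true
# truncated Chebyshev series, not an aliased collocation fit.
.chebyshev_coefficients <- function(fun, m, lmax) {
  N <- max(m + 1L, 1000L)
  theta <- pi * (seq_len(N) - 0.5) / N
  fx <- fun(lmax / 2 * (cos(theta) + 1))
  ct <- cos(outer(0:m, theta))
  as.vector(2 / N * (ct %*% fx))
}

# Apply the Chebyshev-approximated operator fun(L) to the columns of X,
# where L = diag(deg) - W restricted to one component.
.chebyshev_apply <- function(W, deg, coef, lmax, X) {
  a <- lmax / 2
  m <- length(coef) - 1L
  lap <- function(Y) deg * Y - W %*% Y
  T_old <- X
  T_cur <- lap(X) / a - X
  out <- 0.5 * coef[1] * T_old + coef[2] * T_cur
  if (m >= 2L) {
    for (k in 2:m) {
      T_new <- 2 * (lap(T_cur) / a - T_cur) - T_old
      out <- out + coef[k + 1] * T_new
      T_old <- T_cur
      T_cur <- T_new
    }
  }
  out
}

# Pearson correlation between the rows of F (nodes x features), population
# moments. Zero-variance rows are flagged: correlation 0 to every other
# node, 1 on the diagonal.
.feature_correlation <- function(F) {
  Fc <- F - rowMeans(F)
  ss <- sqrt(rowSums(Fc^2))
  zero <- ss <= 1e-300
  ss[zero] <- 1
  C <- tcrossprod(Fc / ss)
  if (any(zero)) {
    C[zero, ] <- 0
    C[, zero] <- 0
  }
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  C
}

.new_correlation_distance <- function(C, scale, eta, seed) {
  D <- 1 - C
  structure(list(scale = scale, C = C, D = D, eta = eta, seed = seed),
            class = "CorrelationDistance")
}

#' Exact wavelet correlation distance (eigendecomposition oracle)
#'
#' Computes, per connected component, the full wavelet operator
#' `g(s*L) = U g(s*Lambda) U'` by dense eigendecomposition and correlates
#' the wavelets centred on every pair of nodes. Intended as the exact
#' reference for [fast_correlation_distance()] on graphs small enough for
#' dense eigensolvers (n up to ~2000).
#'
#' @param G an `InteractionGraph`.
#' @param s wavelet scale.
#' @return an object of class `CorrelationDistance` with fields `scale`,
#'   `C`, `D = 1 - C`, `eta = "exact"`. Node pairs in different components
#'   have undefined correlation: `C = -1`, `D = 2`.
#' @export
exact_correlation_distance <- function(G, s) {
  n <- G$n
  C <- matrix(-1, n, n)
  diag(C) <- 1
  for (c in seq_along(G$components)) {
    idx <- G$components[[c]]
    if (length(idx) < 2L) next
    Wc <- G$weights[idx, idx, drop = FALSE]
    L <- -Wc
    diag(L) <- diag(L) + rowSums(Wc)
    eg <- eigen(L, symmetric = TRUE)
    gsl <- wavelet_kernel(s * eg$values)
    Psi <- eg$vectors %*% (gsl * t(eg$vectors))
    # wavelet centred on node a is column a; correlate columns
    C[idx, idx] <- .feature_correlation(t(Psi))
  }
  .new_correlation_distance(C, scale = s, eta = "exact", seed = NA_integer_)
}

#' Fast wavelet correlation distance via random vectors and Chebyshev
#'
#' Instead of the `n` wavelet transforms of impulses needed for the exact
#' correlation matrix, `eta` standard-Gaussian random vectors are filtered
#' through the Chebyshev-approximated operator `g(s*L)`; the empirical
#' correlation of the `eta` features at every node pair converges to the
#' exact wavelet correlation as `eta` grows.
#'
#' @param G an `InteractionGraph`.
#' @param s wavelet scale.
#' @param eta number of random vectors (>= 2); the method default is 200.
#' @param seed integer seed making the draw reproducible; `NULL` uses the
#'   current RNG state.
#' @param order Chebyshev polynomial order (>= 10).
#' @return a `CorrelationDistance` (see [exact_correlation_distance()]),
#'   with `eta` and `seed` recorded.
#' @export
fast_correlation_distance <- function(G, s, eta = 200L, seed = NULL,
                                      order = 50L) {
  if (eta < 2L) stop("eta must be >= 2")
  if (order < 10L) stop("Chebyshev order must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  peak <- .kernel_peak()
  ok <- which(lengths(G$components) >= 2L)
  if (length(ok)) {
    s_min <- min(peak / G$lambda_max[ok])
    s_max <- max(peak / G$lambda_2[ok])
    if (s < s_min / 10 || s > 10 * s_max)
      warning(sprintf(paste0("scale %.3g far outside the component scale",
                             " range [%.3g, %.3g]; Chebyshev fit covers the",
                             " kernel support poorly"), s, s_min, s_max))
  }
  n <- G$n
  C <- matrix(-1, n, n)
  diag(C) <- 1
  for (c in seq_along(G$components)) {
    idx <- G$components[[c]]
    nc <- length(idx)
    if (nc < 2L) next
    Wc <- G$weights[idx, idx, drop = FALSE]
    deg <- rowSums(Wc)
    lmax <- G$lambda_max[c]
    coef <- .chebyshev_coefficients(function(x) wavelet_kernel(s * x),
                                    order, lmax)
    R <- matrix(stats::rnorm(nc * as.integer(eta)), nc, as.integer(eta))
    F <- .chebyshev_apply(Wc, deg, coef, lmax, R)
    C[idx, idx] <- .feature_correlation(F)
  }
  .new_correlation_distance(C, scale = s, eta = as.integer(eta),
                            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
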