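# Per-scale community detection and the multi-scale scan.

# Cut an average-linkage dendrogram at the widest gap of its merge-height
# ladder. Candidate cuts and their gaps, for merge heights h_1..h_{n-1}:
#   below merge 1 (gap h_1 - 0)        -> n singletons
#   between merges j and j+1           -> n - j communities
#   above the final merge              -> 1 community, with the gap measured
#                                         up to the uncorrelated reference
#                                         level D = 1 (C = 0)
# Ties are broken toward fewer communities. If every merge happens at the
# same height there is no preferred cut and the component is returned as a
# single community.
.cut_dendrogram <- function(hc, n) {
  h <- hc$height
  if (diff(range(h)) <= 1e-9 * max(1, max(abs(h))))
    return(rep(1L, n))
  gaps <- c(h[1], diff(h), max(0, 1 - h[length(h)]))
  j <- max(which(gaps == max(gaps)))
  k <- if (j > length(h)) 1L else n - j + 1L
  if (k == 1L) rep(1L, n) else unname(stats::cutree(hc, k = k))
}

#' Partition one component at one scale
#'
#' Average-linkage hierarchical clustering of the wavelet correlation
#' distance, cut at the largest gap between consecutive merge heights
#' (see Details). All-singleton and single-community partitions are valid
#' outcomes: they signal the absence of community structure at that scale.
#'
#' @details The cut rule considers the gap below the first merge (yielding
#'   all singletons), the gaps between consecutive merges, and the gap
#'   between the final merge and the uncorrelated distance level `D = 1`
#'   (yielding one community); the widest gap wins, ties going to fewer
#'   communities. When all merge heights coincide the distance carries no
#'   structure and a single community is returned.
#'
#' @param D a `CorrelationDistance` for a single connected component, or a
#'   square symmetric distance matrix with zero diagonal.
#' @return integer community labels (1-based, consecutive).
#' @export
partition_at_scale <- function(D) {
  if (inherits(D, "CorrelationDistance")) D <- D$D
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("distance matrix must be square")
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- .cut_dendrogram(hc, n)
  # relabel to consecutive ids in order of first appearance
  match(labels, unique(labels))
}

# deterministic per-(component, scale) seed derived from the master seed
.derive_seed <- function(seed, scale_index, component) {
  (as.integer(seed) + 7919L * (as.integer(scale_index) - 1L) +
     104729L * (as.integer(component) - 1L)) %% 2147483587L
}

#' Multi-scale community mining of an interaction graph
#'
#' For each connected component, builds its scale grid and, at each of the
#' `J` scales, estimates the wavelet correlation distance with `eta` random
#' vectors and partitions the component by average-linkage clustering.
#' Components are processed independently (communities never span two
#' components); singleton components stay singleton communities at every
#' scale. Each (component, scale) task draws from its own RNG stream seeded
#' deterministically from `seed`, so results do not depend on execution
#' order.
#'
#' @param G an `InteractionGraph`.
#' @param J number of scales (the method default is 100).
#' @param eta number of random vectors per scale (default 200).
#' @param seed master integer seed.
#' @param order Chebyshev polynomial order.
#' @return list of `J` objects of class `ScalePartition`, each with
#'   `scale_index`, `scale_values` (per component; `NA` for singleton
#'   components), `labels` (community id per node, unique across
#'   components) and `sizes`.
#' @export
mine_multiscale <- function(G, J = 100L, eta = 200L, seed = 1L, order = 50L) {
  J <- as.integer(J)
  if (J < 2L) stop("J must be >= 2")
  ncomp <- length(G$components)
  grids <- lapply(seq_len(ncomp), function(c) scale_grid(G, J, component = c))
  comp_prep <- lapply(seq_len(ncomp), function(c) {
    idx <- G$components[[c]]
    if (length(idx) < 2L) return(NULL)
    Wc <- G$weights[idx, idx, drop = FALSE]
    list(idx = idx, W = Wc, deg = rowSums(Wc), lmax = G$lambda_max[c])
  })
  partitions <- vector("list", J)
  for (j in seq_len(J)) {
    labels <- integer(G$n)
    next_id <- 0L
    for (c in seq_len(ncomp)) {
      idx <- G$components[[c]]
      if (length(idx) < 2L) {
        labels[idx] <- next_id + 1L
        next_id <- next_id + 1L
        next
      }
      prep <- comp_prep[[c]]
      s <- grids[[c]]$scales[j]
      set.seed(.derive_seed(seed, j, c))
      coef <- .chebyshev_coefficients(function(x) wavelet_kernel(s * x),
                                      order, prep$lmax)
      R <- matrix(stats::rnorm(length(idx) * eta), length(idx), eta)
      F <- .chebyshev_apply(prep$W, prep$deg, coef, prep$lmax, R)
      C <- .feature_correlation(F)
      cl <- partition_at_scale(1 - C)
      labels[idx] <- next_id + cl
      next_id <- next_id + max(cl)
    }
    partitions[[j]] <- structure(
      list(scale_index = j,
           scale_values = vapply(grids, function(g)
             if (g$J > 0L) g$scales[j] else NA_real_, numeric(1)),
           labels = labels,
           sizes = as.integer(table(labels))),
      class = "ScalePartition")
  }
  partitions
}

#' Mean community size per scale
#'
#' @param partitions list of `ScalePartition` from [mine_multiscale()].
#' @return data.frame with `scale_index` and `mean_size` (arithmetic mean
#'   of community sizes, in bins).
#' @export
mean_size_profile <- function(partitions) {
  if (length(partitions) == 0L) stop("need at least one partition")
  data.frame(
    scale_index = vapply(partitions, function(p) p$scale_index, integer(1)),
    mean_size = vapply(partitions, function(p) mean(p$sizes), numeric(1))
  )
}
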