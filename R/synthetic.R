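# Simulated contact matrices with planted domain structure: the validation
# surface for the full mining pipeline, no external data required.

# symmetric Poisson noise on the unordered interaction pairs (pairs with a
# nonzero structural value), mirrored; the near-diagonal band, not the
# noise, is what keeps the graph connected
.add_pair_noise <- function(M, lambda) {
  if (lambda <= 0) return(M)
  n <- nrow(M)
  up <- upper.tri(M) & M > 0
  noise <- matrix(0, n, n)
  noise[up] <- stats::rpois(sum(up), lambda)
  M + noise + t(noise)
}

.tile_truth <- function(sizes, bin_size, chrom, level = 1L) {
  ends <- cumsum(sizes)
  starts <- c(0, ends[-length(ends)])
  data.frame(chrom = chrom, start = starts * bin_size, end = ends * bin_size,
             length = sizes * bin_size, level = level,
             stringsAsFactors = FALSE)
}

.new_benchmark <- function(values, truth, params, bin_size, chrom) {
  diag(values) <- 0
  structure(
    list(matrix = contact_matrix(values, chrom = chrom, bin_size = bin_size),
         truth = truth, params = params),
    class = "SyntheticBenchmark")
}

#' @export
print.SyntheticBenchmark <- function(x, ...) {
  cat(sprintf("SyntheticBenchmark: %d nodes, %d planted domain(s)\n",
              n_bins(x$matrix), nrow(x$truth)))
  invisible(x)
}

#' Planted-domain validation matrix (alternating 20/30-node blocks)
#'
#' Simulates a structural interaction matrix between `sum(sizes) * n_pairs`
#' nodes organised in fully connected interval domains with no structure at
#' larger scales: `n_pairs` pairs of blocks of `sizes` nodes with internal
#' interaction `internal`, the first (resp. second) sub- and
#' super-diagonals overwritten to `sub1` (resp. `sub2`) to assure
#' connectivity, and additive Poisson noise of mean `lambda` on every
#' unordered interacting node pair (pairs with a nonzero structural
#' value), mirrored to keep the matrix symmetric. The
#' diagonal is zero. Defaults reproduce the standard 2000-node benchmark
#' (40 pairs of 20- and 30-node domains, internal 60, sub-diagonals 80/70,
#' `lambda = 50`).
#'
#' @param seed integer seed for the noise layer; the planted structure does
#'   not depend on it.
#' @param lambda Poisson noise mean; 0 gives the noise-free matrix.
#' @param n_pairs number of block pairs.
#' @param sizes block sizes within a pair.
#' @param internal within-domain interaction value.
#' @param sub1,sub2 values overwriting the first and second
#'   sub/super-diagonals.
#' @param bin_size bin width in bp used to express the planted domains as
#'   genomic intervals (default 100 kb, one node per 100 kb locus).
#' @param chrom chromosome name of the simulated matrix.
#' @return an object of class `SyntheticBenchmark`: `matrix` (a
#'   `ContactMatrix`), `truth` (data.frame of planted domains) and
#'   `params`.
#' @export
generate_block_benchmark <- function(seed = 1L, lambda = 50, n_pairs = 40L,
                                  sizes = c(20L, 30L), internal = 60,
                                  sub1 = 80, sub2 = 70, bin_size = 1e5,
                                  chrom = "sim") {
  block_sizes <- rep(sizes, n_pairs)
  n <- sum(block_sizes)
  M <- matrix(0, n, n)
  ends <- cumsum(block_sizes)
  starts <- c(1L, ends[-length(ends)] + 1L)
  for (b in seq_along(block_sizes)) {
    r <- starts[b]:ends[b]
    M[r, r] <- internal
  }
  i <- seq_len(n - 1L)
  M[cbind(i, i + 1L)] <- sub1; M[cbind(i + 1L, i)] <- sub1
  if (n > 2L) {
    i <- seq_len(n - 2L)
    M[cbind(i, i + 2L)] <- sub2; M[cbind(i + 2L, i)] <- sub2
  }
  set.seed(seed)
  M <- .add_pair_noise(M, lambda)
  .new_benchmark(M, .tile_truth(block_sizes, bin_size, chrom),
                 params = list(n = n, n_pairs = n_pairs, sizes = sizes,
                               internal = internal, sub1 = sub1, sub2 = sub2,
                               lambda = lambda, seed = seed),
                 bin_size = bin_size, chrom = chrom)
}

#' Hierarchically nested block benchmark
#'
#' Builds a matrix with nested on-diagonal blocks: levels are filled from
#' coarse to fine with strictly increasing interaction values (finer blocks
#' are denser and overwrite the coarser background), the near-diagonal is
#' overwritten for connectivity, and Poisson pair noise is added. Every
#' finer level must subdivide the coarser ones exactly.
#'
#' @param level_sizes list of integer vectors, one per level from coarse to
#'   fine; each vector gives the block sizes (in nodes) tiling the matrix.
#' @param values within-block interaction per level, strictly increasing.
#' @param lambda Poisson noise mean.
#' @param seed integer seed for the noise layer.
#' @param sub1,sub2 near-diagonal connectivity values.
#' @inheritParams generate_block_benchmark
#' @return a `SyntheticBenchmark`; `truth` records the domains of every
#'   level (column `level`, 1 = coarsest).
#' @export
generate_nested_blocks <- function(level_sizes, values, lambda = 5,
                                   seed = 1L, sub1 = 80, sub2 = 70,
                                   bin_size = 1e5, chrom = "sim") {
  if (length(level_sizes) != length(values))
    stop("need one interaction value per level")
  if (length(values) > 1L && any(diff(values) <= 0))
    stop("values must be strictly increasing with depth (finer blocks denser)")
  n <- sum(level_sizes[[1]])
  bounds <- lapply(level_sizes, function(sz) {
    if (sum(sz) != n) stop("every level must tile the same ", n, " nodes")
    cumsum(sz)
  })
  for (l in seq_along(bounds)[-1]) {
    if (!all(bounds[[l - 1]] %in% bounds[[l]]))
      stop("level ", l, " does not nest inside level ", l - 1)
  }
  M <- matrix(0, n, n)
  truth <- list()
  for (l in seq_along(level_sizes)) {
    ends <- bounds[[l]]
    starts <- c(1L, ends[-length(ends)] + 1L)
    for (b in seq_along(ends)) {
      r <- starts[b]:ends[b]
      M[r, r] <- values[l]
    }
    truth[[l]] <- .tile_truth(level_sizes[[l]], bin_size, chrom, level = l)
  }
  i <- seq_len(n - 1L)
  M[cbind(i, i + 1L)] <- sub1; M[cbind(i + 1L, i)] <- sub1
  if (n > 2L) {
    i <- seq_len(n - 2L)
    M[cbind(i, i + 2L)] <- sub2; M[cbind(i + 2L, i)] <- sub2
  }
  set.seed(seed)
  M <- .add_pair_noise(M, lambda)
  .new_benchmark(M, do.call(rbind, truth),
                 params = list(n = n, level_sizes = level_sizes,
                               values = values, lambda = lambda, seed = seed,
                               sub1 = sub1, sub2 = sub2),
                 bin_size = bin_size, chrom = chrom)
}

#' Degenerate two-arm (mitosis-like) fixture
#'
#' Two on-diagonal mega-blocks (the chromosome arms) with weak inter-arm
#' contact, a strong near-diagonal band and *no* intermediate-scale
#' blocks: the matrix a condensed mitotic chromosome would produce. A
#' robust miner should report only singletons below a critical scale and a
#' small number of communities matching the arms above it, with no
#' intermediate-size interval-communities.
#'
#' @param n number of nodes.
#' @param arm_split first node (1-based, exclusive end of arm 1 is
#'   `arm_split`) of the second arm boundary, i.e. arm 1 covers nodes
#'   `1..arm_split` and arm 2 `arm_split+1..n`.
#' @param near_diag_width number of sub/super-diagonals set to
#'   `band_value`.
#' @param seed integer seed for the noise layer.
#' @param arm_value within-arm interaction.
#' @param inter_value weak between-arm interaction.
#' @param band_value near-diagonal band interaction.
#' @param lambda Poisson noise mean.
#' @inheritParams generate_block_benchmark
#' @return a `SyntheticBenchmark` whose `truth` is the two arms.
#' @export
generate_armlike <- function(n = 300L, arm_split = n %/% 2L,
                             near_diag_width = 2L, seed = 1L, arm_value = 60,
                             inter_value = 2, band_value = 80, lambda = 5,
                             bin_size = 1e5, chrom = "sim") {
  if (arm_split <= 0L || arm_split >= n) stop("need 0 < arm_split < n")
  M <- matrix(inter_value, n, n)
  a1 <- 1:arm_split; a2 <- (arm_split + 1L):n
  M[a1, a1] <- arm_value
  M[a2, a2] <- arm_value
  for (w in seq_len(near_diag_width)) {
    i <- seq_len(n - w)
    M[cbind(i, i + w)] <- band_value; M[cbind(i + w, i)] <- band_value
  }
  set.seed(seed)
  M <- .add_pair_noise(M, lambda)
  .new_benchmark(M, .tile_truth(c(arm_split, n - arm_split), bin_size, chrom),
                 params = list(n = n, arm_split = arm_split,
                               near_diag_width = near_diag_width,
                               arm_value = arm_value,
                               inter_value = inter_value,
                               band_value = band_value, lambda = lambda,
                               seed = seed),
                 bin_size = bin_size, chrom = chrom)
}

#' Score recovery of planted domains
#'
#' A planted domain is recovered when its best mutual coverage against the
#' found domain set reaches `thresh`.
#'
#' @param found data.frame of found domains (`start`, `end`).
#' @param truth data.frame of planted domains.
#' @param thresh mutual-coverage match threshold (default 0.8).
#' @return list with `matched` (logical per truth domain), `n_matched`,
#'   and `bm_c` (the best mutual coverages).
#' @export
recovery_score <- function(found, truth, thresh = 0.8) {
  if (nrow(found) == 0L) {
    return(list(matched = rep(FALSE, nrow(truth)), n_matched = 0L,
                bm_c = rep(0, nrow(truth))))
  }
  bm <- .bmc_all(truth, found)
  list(matched = bm >= thresh, n_matched = sum(bm >= thresh), bm_c = bm)
}

#' Sample domain lengths from a truncated power law
#'
#' Draws lengths with density proportional to `l^alpha` on
#' `[l_min, l_max]` by inverse-CDF sampling; used to validate the
#' power-law exponent fit of [length_distribution()].
#'
#' @param n number of draws.
#' @param alpha exponent (must not be -1).
#' @param l_min,l_max support bounds (bp).
#' @param seed optional integer seed.
#' @return numeric vector of lengths.
#' @export
sample_domain_lengths <- function(n, alpha = -1.3, l_min = 2e6, l_max = 1e8,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (alpha == -1) stop("alpha = -1 not supported")
  a1 <- alpha + 1
  u <- stats::runif(n)
  (l_min^a1 + u * (l_max^a1 - l_min^a1))^(1 / a1)
}
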