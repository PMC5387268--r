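# Small graph and matrix fixtures built in code.

# two m-cliques joined by a single bridge edge
make_two_clique <- function(m = 25) {
  n <- 2L * m
  W <- matrix(0, n, n)
  W[1:m, 1:m] <- 1
  W[(m + 1):n, (m + 1):n] <- 1
  diag(W) <- 0
  W[m, m + 1] <- 1
  W[m + 1, m] <- 1
  W
}

# unit-weight path graph on n nodes
make_path <- function(n) {
  W <- matrix(0, n, n)
  i <- seq_len(n - 1)
  W[cbind(i, i + 1)] <- 1
  W[cbind(i + 1, i)] <- 1
  W
}

# random symmetric non-negative matrix with positive marginals
make_random_contact <- function(n, seed = 1) {
  set.seed(seed)
  V <- matrix(rpois(n * n, 5), n, n)
  V <- V + t(V)
  diag(V) <- 0
  contact_matrix(V, chrom = "chrT", bin_size = 1e5)
}

# hand-built ScalePartition (for interval-analysis tests)
make_partition <- function(labels, scale_index = 1L, scale_value = 1) {
  structure(
    list(scale_index = as.integer(scale_index), scale_values = scale_value,
         labels = as.integer(labels),
         sizes = as.integer(table(labels))),
    class = "ScalePartition")
}
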