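#' Contact matrix for one chromosome
#'
#' Container for a symmetric, non-negative matrix of binned Hi-C
#' co-localisation counts. Bin `i` (1-based internally) covers the genomic
#' interval `[bin_start + (i-1)*bin_size, bin_start + i*bin_size)` in 0-based
#' half-open bp coordinates.
#'
#' @param values square numeric matrix of contact counts. Symmetrised on
#'   construction (average of the matrix and its transpose); entries must be
#'   finite and non-negative.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param bin_start genomic start (bp) of the first bin.
#' @return an object of class `ContactMatrix` with fields `values`, `chrom`,
#'   `bin_size`, `bin_start`.
#' @export
contact_matrix <- function(values, chrom = "chr", bin_size = 1L, bin_start = 0) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("contact matrix must be square, got ", nrow(values), "x", ncol(values))
  if (any(!is.finite(values)))
    stop("contact matrix entries must be finite")
  if (any(values < 0))
    stop("contact matrix entries must be non-negative")
  if (bin_size <= 0) stop("bin_size must be positive")
  dimnames(values) <- NULL
  values <- (values + t(values)) / 2
  structure(
    list(values = values, chrom = as.character(chrom),
         bin_size = as.numeric(bin_size), bin_start = as.numeric(bin_start)),
    class = "ContactMatrix"
  )
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins of %g bp (total %.0f counts)\n",
              x$chrom, nrow(x$values), x$bin_size, sum(x$values)))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param M a `ContactMatrix`.
#' @return integer bin count.
#' @export
n_bins <- function(M) nrow(M$values)

.as_values <- function(M) {
  if (inherits(M, "ContactMatrix")) M$values else as.matrix(M)
}

#' Read a contact matrix from text
#'
#' Two dialects are supported: dense whitespace-separated `N x N` numeric
#' text, and sparse triplet text with rows `i j count` using 0-based bin
#' indices. Triplets present once are mirrored; duplicate (including
#' transposed) triplets are summed before mirroring.
#'
#' The dialect is auto-detected from the column count of the first data
#' line: three columns are read as triplets unless `n_bins_total == 3`
#' suggests otherwise; use `format` to override.
#'
#' @param path input file.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name to record.
#' @param n_bins_total declared matrix size; required for triplet input
#'   whose largest index does not reach the last bin, optional otherwise.
#' @param format `"auto"`, `"dense"` or `"triplet"`.
#' @param bin_start genomic start of bin 0.
#' @return a [contact_matrix()].
#' @export
load_contact_matrix <- function(path, bin_size = 1L, chrom = "chr",
                                n_bins_total = NULL,
                                format = c("auto", "dense", "triplet"),
                                bin_start = 0) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = FALSE)
  if (nrow(dt) == 0L) stop("empty contact matrix file: ", path)
  if (format == "auto") {
    format <- if (ncol(dt) == 3L && nrow(dt) != 3L) "triplet" else "dense"
  }
  if (format == "dense") {
    values <- as.matrix(dt)
    if (nrow(values) != ncol(values))
      stop("dense contact matrix file is not square: ",
           nrow(values), " rows x ", ncol(values), " columns")
    storage.mode(values) <- "double"
  } else {
    if (ncol(dt) != 3L) stop("triplet input must have 3 columns (i j count)")
    i <- as.integer(dt[[1]]); j <- as.integer(dt[[2]]); w <- as.numeric(dt[[3]])
    if (any(i < 0L) || any(j < 0L)) stop("triplet indices must be >= 0")
    if (any(w < 0)) stop("negative counts in triplet input")
    n <- if (is.null(n_bins_total)) max(i, j) + 1L else as.integer(n_bins_total)
    if (any(i >= n) || any(j >= n))
      stop("triplet index beyond declared matrix size ", n)
    # duplicates (and transposed duplicates) accumulate, then mirror
    lin <- as.numeric(i) + as.numeric(n) * as.numeric(j)
    agg <- rowsum(w, lin)
    lin_u <- as.numeric(rownames(agg))
    acc <- matrix(0, n, n)
    acc[cbind(lin_u %% n + 1, lin_u %/% n + 1)] <- agg[, 1]
    values <- acc + t(acc)
    diag(values) <- diag(acc)
  }
  contact_matrix(values, chrom = chrom, bin_size = bin_size, bin_start = bin_start)
}

#' Write a contact matrix to text
#'
#' Inverse of [load_contact_matrix()]: `"dense"` writes the full
#' whitespace-separated matrix, `"triplet"` writes the nonzero upper
#' triangle (including diagonal) as 0-based `i j count` rows.
#'
#' @param M a `ContactMatrix`.
#' @param path output file.
#' @param format `"dense"` or `"triplet"`.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(M, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  v <- .as_values(M)
  if (format == "dense") {
    data.table::fwrite(data.table::as.data.table(v), path, sep = " ",
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
    dt <- data.table::data.table(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                                 count = v[idx])
    data.table::fwrite(dt, path, sep = " ", col.names = FALSE)
  }
  invisible(path)
}

#' Down-sample a contact matrix to coarser bins
#'
#' Entry `(I, J)` of the result sums all entries `(i, j)` with
#' `floor((i-1)/factor) = I-1` and `floor((j-1)/factor) = J-1`, so the total
#' matrix sum is conserved exactly and symmetry is preserved. The last
#' coarse bin may aggregate fewer than `factor` fine bins.
#'
#' @param M a `ContactMatrix`.
#' @param factor integer aggregation factor (>= 1).
#' @return a `ContactMatrix` with `bin_size * factor`.
#' @export
downsample <- function(M, factor) {
  if (!inherits(M, "ContactMatrix")) stop("downsample expects a ContactMatrix")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(M)
  n <- n_bins(M)
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  v <- rowsum(M$values, grp, reorder = TRUE)
  v <- t(rowsum(t(v), grp, reorder = TRUE))
  contact_matrix(v, chrom = M$chrom, bin_size = M$bin_size * factor,
                 bin_start = M$bin_start)
}

#' Map between masked and original bin indices
#'
#' After low/high-coverage loci are removed, the surviving bins are
#' concatenated into "masked positions". `kept[k]` is the original (1-based)
#' bin index of masked bin `k`.
#'
#' @param kept strictly increasing integer vector of retained original bins.
#' @param n_bins_total total number of original bins.
#' @return an object of class `MaskedIndexMap` with fields `kept`, `masked`,
#'   `n_bins_total`.
#' @export
masked_index_map <- function(kept, n_bins_total) {
  kept <- as.integer(kept)
  n_bins_total <- as.integer(n_bins_total)
  if (length(kept) == 0L) stop("masked index map must keep at least one bin")
  if (is.unsorted(kept, strictly = TRUE)) stop("kept indices must be strictly increasing")
  if (kept[1] < 1L || kept[length(kept)] > n_bins_total)
    stop("kept indices out of range 1..", n_bins_total)
  structure(
    list(kept = kept, masked = setdiff(seq_len(n_bins_total), kept),
         n_bins_total = n_bins_total),
    class = "MaskedIndexMap"
  )
}

#' Identity mask (no bins removed)
#' @param n_bins_total total number of bins.
#' @return a [masked_index_map()] keeping every bin.
#' @export
identity_mask <- function(n_bins_total) {
  masked_index_map(seq_len(n_bins_total), n_bins_total)
}

#' Remove unexpectedly low and high interacting loci
#'
#' A bin is masked when its marginal interaction sum is zero, below the
#' `low_q` quantile, or above the `high_q` quantile of the *nonzero*
#' marginal sums (linear-interpolation quantiles, [stats::quantile()]
#' type 7). The surviving rows/columns are concatenated, defining the
#' masked positions.
#'
#' @param M a `ContactMatrix`.
#' @param low_q,high_q quantile cutoffs, `0 <= low_q < high_q <= 1`.
#' @return list with `matrix` (the masked `ContactMatrix`) and `map`
#'   (a [masked_index_map()]).
#' @export
filter_loci <- function(M, low_q = 0.005, high_q = 0.995) {
  if (!inherits(M, "ContactMatrix")) stop("filter_loci expects a ContactMatrix")
  if (!(low_q >= 0 && low_q < high_q && high_q <= 1))
    stop("need 0 <= low_q < high_q <= 1")
  marg <- rowSums(M$values)
  nz <- marg[marg > 0]
  if (length(nz) == 0L)
    stop("all ", length(marg), " bins have zero marginal sum; empty graph")
  qs <- stats::quantile(nz, c(low_q, high_q), type = 7, names = FALSE)
  drop <- marg == 0 | marg < qs[1] | marg > qs[2]
  if (all(drop))
    stop("filtering removed all ", length(marg), " bins ",
         "(low_q=", low_q, ", high_q=", high_q, "); empty graph")
  kept <- which(!drop)
  out <- contact_matrix(M$values[kept, kept, drop = FALSE], chrom = M$chrom,
                        bin_size = M$bin_size, bin_start = M$bin_start)
  list(matrix = out, map = masked_index_map(kept, length(marg)))
}

#' Project a masked interval back to genomic coordinates
#'
#' Masked intervals are 0-based half-open in masked-bin units. The genomic
#' interval spans from the start of the first kept bin to the end of the
#' last kept bin; the inflation ratio (genomic length over masked length)
#' exceeds 1 whenever the interval straddles masked bins, e.g. a
#' centromere.
#'
#' @param masked_start,masked_end masked-bin interval, 0-based half-open.
#' @param map a [masked_index_map()].
#' @param bin_size bin width in bp.
#' @param bin_start genomic start of original bin 0.
#' @param chrom chromosome name for the returned interval.
#' @return list with `interval` (one-row data.frame `chrom`, `start`, `end`)
#'   and `inflation`.
#' @export
unmask <- function(masked_start, masked_end, map, bin_size = 1, bin_start = 0,
                   chrom = "chr") {
  if (!inherits(map, "MaskedIndexMap")) stop("map must be a MaskedIndexMap")
  nk <- length(map$kept)
  if (masked_start < 0 || masked_end > nk || masked_start >= masked_end)
    stop("masked interval [", masked_start, ",", masked_end,
         ") out of range 0..", nk)
  first <- map$kept[masked_start + 1L]
  last <- map$kept[masked_end]
  start <- bin_start + (first - 1L) * bin_size
  end <- bin_start + last * bin_size
  inflation <- (end - start) / ((masked_end - masked_start) * bin_size)
  list(interval = data.frame(chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE),
       inflation = inflation)
}
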