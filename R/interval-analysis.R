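# From per-scale communities to a de-duplicated database of genomic
# interval-communities, their borders and cross-scale statistics.

# longest run of consecutive integers; returns c(first, last) of the first
# longest run (1-based masked bin indices)
.largest_run <- function(nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  brk <- c(0L, which(diff(nodes) != 1L), length(nodes))
  len <- diff(brk)
  i <- which.max(len)
  c(nodes[brk[i] + 1L], nodes[brk[i + 1L]])
}

#' Interval fraction of a community
#'
#' `P_int` is the length of the largest set of consecutive masked bins in
#' the community divided by the community size: 1 when the community is a
#' contiguous interval of the masked genome, `1/N` when no two of its `N`
#' bins are consecutive.
#'
#' @param nodes masked bin indices of the community (1-based).
#' @return `P_int` in `[1/N, 1]`.
#' @export
interval_fraction <- function(nodes) {
  if (length(nodes) == 0L) stop("empty community")
  run <- .largest_run(nodes)
  (run[2] - run[1] + 1L) / length(unique(nodes))
}

#' Per-scale interval-communities
#'
#' Scans the partitions, drops singleton communities, and keeps the
#' communities whose interval fraction reaches `p_threshold`, reduced to
#' their main interval (the largest run of consecutive masked bins).
#' Masked intervals are reported 0-based half-open in masked-bin units.
#'
#' @param partitions list of `ScalePartition` from [mine_multiscale()].
#' @param p_threshold minimum `P_int` for a community to count as an
#'   interval (method default 0.95).
#' @return data.frame: `scale_index`, `masked_start`, `masked_end`, `size`
#'   (community size in bins), `p_int`.
#' @export
scale_interval_communities <- function(partitions, p_threshold = 0.95) {
  rows <- lapply(partitions, function(p) {
    grp <- split(seq_along(p$labels), p$labels)
    grp <- grp[lengths(grp) >= 2L]
    if (length(grp) == 0L) return(NULL)
    pint <- vapply(grp, interval_fraction, numeric(1))
    keep <- pint >= p_threshold
    if (!any(keep)) return(NULL)
    runs <- vapply(grp[keep], .largest_run, integer(2))
    data.frame(scale_index = p$scale_index,
               masked_start = runs[1, ] - 1L,
               masked_end = runs[2, ],
               size = lengths(grp[keep]),
               p_int = pint[keep],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(scale_index = integer(0), masked_start = integer(0),
                      masked_end = integer(0), size = integer(0),
                      p_int = numeric(0))
  out
}

#' Extract the de-duplicated interval-community database
#'
#' Reduces the multi-scale partitions to interval-communities
#' ([scale_interval_communities()]), keeps each distinct masked interval
#' only once while recording the set of scales where it was observed,
#' projects it back to genomic coordinates through the mask, and drops
#' intervals whose genomic span is more than `inflation_max` times their
#' masked span (e.g. communities straddling a masked centromere).
#'
#' @param partitions list of `ScalePartition`.
#' @param map a [masked_index_map()]; `NULL` means no bins were masked.
#' @param bin_size bin width in bp.
#' @param bin_start genomic start of original bin 0.
#' @param chrom chromosome name.
#' @param p_threshold minimum interval fraction (default 0.95).
#' @param inflation_max maximum genomic/masked length ratio (default 2).
#' @return data.frame, one row per distinct interval-community: `chrom`,
#'   `start`, `end`, `length` (bp), `masked_start`, `masked_end`, `p_int`
#'   (maximum over the scales where observed), `scales` (list column of
#'   scale indices), `n_scales`, `inflation`.
#' @export
extract_interval_communities <- function(partitions, map = NULL, bin_size = 1,
                                         bin_start = 0, chrom = "chr",
                                         p_threshold = 0.95,
                                         inflation_max = 2) {
  sc <- scale_interval_communities(partitions, p_threshold)
  if (is.null(map)) {
    nk <- length(partitions[[1]]$labels)
    map <- identity_mask(nk)
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      masked_start = integer(0), masked_end = integer(0),
                      p_int = numeric(0), scales = I(list()),
                      n_scales = integer(0), inflation = numeric(0))
  if (nrow(sc) == 0L) return(empty)
  key <- paste(sc$masked_start, sc$masked_end, sep = ":")
  grp <- split(seq_len(nrow(sc)), key)
  rows <- lapply(grp, function(i) {
    um <- unmask(sc$masked_start[i[1]], sc$masked_end[i[1]], map,
                 bin_size = bin_size, bin_start = bin_start, chrom = chrom)
    data.frame(chrom = chrom, start = um$interval$start,
               end = um$interval$end,
               length = um$interval$end - um$interval$start,
               masked_start = sc$masked_start[i[1]],
               masked_end = sc$masked_end[i[1]],
               p_int = max(sc$p_int[i]),
               scales = I(list(sort(sc$scale_index[i]))),
               n_scales = length(i),
               inflation = um$inflation,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[out$inflation <= inflation_max, , drop = FALSE]
  out <- out[order(out$masked_start, out$masked_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-scale border positions: boundaries shared by two consecutive
# (touching) interval-communities at that scale, with the per-scale
# associated length = min of the two bordering lengths (in bins)
.scale_borders <- function(sc_scale) {
  o <- order(sc_scale$masked_start)
  s <- sc_scale$masked_start[o]
  e <- sc_scale$masked_end[o]
  if (length(s) < 2L)
    return(data.frame(position = integer(0), length = integer(0)))
  touch <- which(e[-length(e)] == s[-1])
  data.frame(position = e[touch],
             length = pmin(e[touch] - s[touch], e[touch + 1L] - s[touch + 1L]))
}

#' Border database of the interval-communities
#'
#' At each scale a border exists between every pair of consecutive
#' (touching) interval-communities and carries the minimum of the two
#' bordering lengths; the final database is the union of distinct border
#' positions across scales, each with the maximum of its per-scale
#' associated lengths.
#'
#' @param sc per-scale interval-communities from
#'   [scale_interval_communities()].
#' @param bin_size multiplier applied to positions and lengths (set to the
#'   bin width in bp for genomic units; default 1 leaves masked-bin units).
#' @return data.frame: `position` (masked-coordinate boundary),
#'   `associated_length`, sorted by position.
#' @export
community_borders <- function(sc, bin_size = 1) {
  per_scale <- lapply(split(sc, sc$scale_index), .scale_borders)
  all <- do.call(rbind, per_scale)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(position = numeric(0), associated_length = numeric(0)))
  agg <- tapply(all$length, all$position, max)
  out <- data.frame(position = as.numeric(names(agg)) * bin_size,
                    associated_length = as.numeric(agg) * bin_size)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-scale conservation of borders
#'
#' For every scale pair `s2 > s1`, the proportion of borders at the larger
#' scale `s2` whose masked position also occurs among the borders at the
#' smaller scale `s1` (exact pixel match by default). Proportions close to
#' 1 at all pairs indicate a nested hierarchy: structures merge without new
#' borders emerging at larger scales.
#'
#' @param sc per-scale interval-communities from
#'   [scale_interval_communities()].
#' @param J total number of scales (defaults to the largest scale index
#'   present).
#' @param tol_pixels match tolerance in masked bins (default 0 = exact).
#' @return `J x J` matrix `P` with `P[s1, s2]` the conserved proportion for
#'   `s2 > s1`; entries are `NA` where either scale has no borders, and on
#'   and below the diagonal.
#' @export
border_conservation <- function(sc, J = NULL, tol_pixels = 0L) {
  if (is.null(J)) J <- if (nrow(sc)) max(sc$scale_index) else 0L
  borders <- lapply(seq_len(J), function(j)
    .scale_borders(sc[sc$scale_index == j, , drop = FALSE])$position)
  P <- matrix(NA_real_, J, J)
  for (s1 in seq_len(J)) {
    b1 <- borders[[s1]]
    if (length(b1) == 0L) next
    for (s2 in seq_len(J)) {
      if (s2 <= s1) next
      b2 <- borders[[s2]]
      if (length(b2) == 0L) next
      hit <- if (tol_pixels > 0L) {
        vapply(b2, function(p) any(abs(b1 - p) <= tol_pixels), logical(1))
      } else {
        b2 %in% b1
      }
      P[s1, s2] <- mean(hit)
    }
  }
  P
}

#' Length distribution of interval-communities and power-law fit
#'
#' Histogram of genomic lengths in `bin_size` bins. The exponent `alpha`
#' is the ordinary least-squares slope of `log10(count)` versus
#' `log10(length)` over bins with `length >= fit_min`, zero-count bins
#' excluded; it is `NA` when fewer than 20 lengths or fewer than 3
#' occupied bins are available.
#'
#' @param lengths numeric vector of interval-community lengths (bp).
#' @param bin_size histogram bin width (bp).
#' @param fit_min smallest length included in the fit (bp).
#' @return list with `histogram` (data.frame `l` = bin midpoint, `count`),
#'   `alpha`, and `fit_n` (number of bins used in the fit).
#' @export
length_distribution <- function(lengths, bin_size, fit_min = 0) {
  if (length(lengths) == 0L) stop("no lengths supplied")
  breaks <- seq(0, (max(lengths) %/% bin_size + 1) * bin_size, by = bin_size)
  count <- as.vector(table(cut(lengths, breaks, right = FALSE)))
  hist <- data.frame(l = breaks[-length(breaks)] + bin_size / 2,
                     count = count)
  sel <- hist$count > 0 & hist$l >= fit_min
  alpha <- NA_real_
  if (length(lengths) >= 20L && sum(sel) >= 3L) {
    fit <- stats::lm(log10(count) ~ log10(l), data = hist[sel, ])
    alpha <- unname(stats::coef(fit)[2])
  }
  list(histogram = hist, alpha = alpha, fit_n = sum(sel))
}
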