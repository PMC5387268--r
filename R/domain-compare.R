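# Estimators for comparing two sets of genomic domains (which need not be
# partitions, so partition-similarity indices do not apply) and the
# within/between-community interaction-ratio diagnostic.

.interval_fields <- function(d) {
  if (is.data.frame(d)) {
    list(start = d$start, end = d$end,
         chrom = if ("chrom" %in% names(d)) as.character(d$chrom) else
           rep(NA_character_, nrow(d)))
  } else {
    list(start = d[[1]], end = d[[2]], chrom = NA_character_)
  }
}

#' Mutual coverage of two domains
#'
#' Intersection length divided by the larger of the two domain lengths:
#' 1 for identical domains, 0 for disjoint ones (or different
#' chromosomes).
#'
#' @param d1,d2 single domains: numeric `c(start, end)` or one-row
#'   data.frames with `start`, `end` and optional `chrom`.
#' @return `m_c` in `[0, 1]`.
#' @export
mutual_coverage <- function(d1, d2) {
  a <- .interval_fields(d1); b <- .interval_fields(d2)
  if (!is.na(a$chrom[1]) && !is.na(b$chrom[1]) && a$chrom[1] != b$chrom[1])
    return(0)
  inter <- max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
  inter / max(a$end[1] - a$start[1], b$end[1] - b$start[1])
}

#' Best mutual coverage of a domain against a domain set
#'
#' @param d a single domain (see [mutual_coverage()]).
#' @param D2 data.frame of domains with `start`, `end`, optional `chrom`.
#' @return the maximal [mutual_coverage()] of `d` over `D2`.
#' @export
best_mutual_coverage <- function(d, D2) {
  if (!is.data.frame(D2) || nrow(D2) == 0L) stop("D2 must be a non-empty domain set")
  a <- .interval_fields(d); b <- .interval_fields(D2)
  inter <- pmax(0, pmin(a$end[1], b$end) - pmax(a$start[1], b$start))
  mc <- inter / pmax(a$end[1] - a$start[1], b$end - b$start)
  if (!is.na(a$chrom[1])) mc[!is.na(b$chrom) & b$chrom != a$chrom[1]] <- 0
  max(mc)
}

.bmc_all <- function(D1, D2) {
  vapply(seq_len(nrow(D1)),
         function(i) best_mutual_coverage(D1[i, , drop = FALSE], D2),
         numeric(1))
}

.group_curve <- function(len, value, group, kind) {
  o <- order(len)
  len <- len[o]; value <- value[o]
  g <- (seq_along(len) - 1L) %/% group + 1L
  out <- data.frame(
    mean_length = as.vector(tapply(len, g, mean)),
    value = as.vector(tapply(value, g, mean)),
    n = as.vector(tapply(value, g, length))
  )
  out$partial <- out$n < group
  attr(out, "kind") <- kind
  attr(out, "group_size") <- group
  out
}

#' Mean best-mutual-coverage curve between two domain sets
#'
#' `D1` domains are sorted by length and taken in consecutive groups of
#' `group`; for each group the mean best mutual coverage with `D2` is
#' plotted against the mean domain length of the group. A trailing partial
#' group is retained and flagged.
#'
#' @param D1,D2 data.frames of domains (`start`, `end`, optional `chrom`).
#' @param group group size (method default 50).
#' @return data.frame `mean_length`, `value`, `n`, `partial` with
#'   attributes `kind = "coverage"` and `group_size`.
#' @export
coverage_curve <- function(D1, D2, group = 50L) {
  if (nrow(D1) < group) warning("fewer than one full group of domains")
  .group_curve(D1$end - D1$start, .bmc_all(D1, D2), group, "coverage")
}

#' Domain matching-proportion curve
#'
#' As [coverage_curve()], but the group value is the proportion of `D1`
#' domains whose best mutual coverage with `D2` reaches `thresh` (a
#' "match", method default 0.8).
#'
#' @inheritParams coverage_curve
#' @param thresh match threshold on the best mutual coverage.
#' @return data.frame as in [coverage_curve()], `kind = "domain_match"`.
#' @export
domain_match_curve <- function(D1, D2, thresh = 0.8, group = 50L) {
  .group_curve(D1$end - D1$start, .bmc_all(D1, D2) >= thresh, group,
               "domain_match")
}

#' Border matching-proportion curve
#'
#' A border matches when the reference set has a border at distance
#' `<= tol` (inclusive; at 100 kb binning `tol = 100 kb` means +/- 1
#' pixel). `B1` borders are sorted by associated length and taken in
#' groups of `group`.
#'
#' @param B1,B2 data.frames of borders with `position` and (for `B1`)
#'   `associated_length`.
#' @param tol matching distance (same units as `position`).
#' @param group group size (method default 100).
#' @return data.frame `mean_length` (mean associated length), `value`,
#'   `n`, `partial`; `kind = "border_match"`.
#' @export
border_match_curve <- function(B1, B2, tol = 1e5, group = 100L) {
  if (nrow(B2) == 0L) stop("empty reference border set")
  p2 <- sort(B2$position)
  matched <- vapply(B1$position, function(p) min(abs(p2 - p)) <= tol,
                    logical(1))
  .group_curve(B1$associated_length, matched, group, "border_match")
}

#' Select reference borders up to a genome-coverage budget
#'
#' Greedily adds borders in decreasing associated-length order; each border
#' contributes its +/- `tol_pixels` pixel footprint to a genome coverage
#' mask, and selection stops before the covered fraction would exceed
#' `cover`. Used to build a reference border set whose chance matching
#' level equals `cover`.
#'
#' @param B data.frame of borders with `position` (pixel units) and
#'   `associated_length`.
#' @param genome_size genome size in pixels.
#' @param cover maximum covered fraction (method default 0.35).
#' @param tol_pixels half-width of a border footprint in pixels.
#' @return the selected subset of `B`, with attribute `coverage` (the
#'   final covered fraction).
#' @export
select_borders_by_coverage <- function(B, genome_size, cover = 0.35,
                                       tol_pixels = 1L) {
  o <- order(-B$associated_length, B$position)
  covered <- logical(genome_size)
  budget <- cover * genome_size
  take <- logical(nrow(B))
  for (i in o) {
    p <- round(B$position[i])
    foot <- max(0, p - tol_pixels):min(genome_size - 1, p + tol_pixels) + 1L
    new_cov <- sum(covered) + sum(!covered[foot])
    if (new_cov > budget) break
    covered[foot] <- TRUE
    take[i] <- TRUE
  }
  out <- B[take, , drop = FALSE]
  attr(out, "coverage") <- mean(covered)
  out
}

# default community length categories (bp), as used for the insulation
# ratio curves
default_length_categories <- function() {
  data.frame(min = c(0.3, 0.6, 1, 2, 3, 5, 10) * 1e6,
             max = c(0.6, 1, 2, 3, 5, 10, 100) * 1e6)
}

#' Within/between-community interaction ratio
#'
#' For each community and each genomic separation `d`, the number of
#' contacts between the two loci at equal distance from the community
#' *center* (numerator `c`) is compared with the number of contacts
#' between the two loci at equal distance from each community *border*
#' (denominator `b`). Counts are aggregated over all communities of a
#' length category before dividing, each side normalised by its number of
#' contributing pairs, so a uniform matrix gives ratio 1 at every
#' distance. Pairs falling outside the matrix are skipped. When `d` has
#' the wrong parity for a symmetric pair, the split is asymmetric by half
#' a bin (floor on the left side).
#'
#' @param M a `ContactMatrix`.
#' @param communities data.frame of domains (`start`, `end` in bp,
#'   multiples of the bin size).
#' @param categories data.frame with `min`/`max` length bounds in bp;
#'   defaults to the seven classes 0.3-0.6, 0.6-1, 1-2, 2-3, 3-5, 5-10 and
#'   10-100 Mb.
#' @return data.frame: `category`, `distance` (bp), `c_mean`, `b_mean`,
#'   `ratio`, with `NA` ratio where no border pair was available.
#' @export
interaction_ratio <- function(M, communities,
                              categories = default_length_categories()) {
  if (!inherits(M, "ContactMatrix")) stop("interaction_ratio expects a ContactMatrix")
  V <- M$values
  N <- nrow(V)
  bs <- M$bin_size
  u_all <- round((communities$start - M$bin_start) / bs) + 1L
  v_all <- round((communities$end - M$bin_start) / bs)
  len_bp <- communities$end - communities$start
  cat_of <- vapply(len_bp, function(l) {
    k <- which(categories$min <= l & l < categories$max)
    if (length(k)) k[1] else NA_integer_
  }, integer(1))
  res <- list()
  for (k in seq_len(nrow(categories))) {
    rows <- which(cat_of == k)
    if (length(rows) == 0L) next
    dmax <- max(v_all[rows] - u_all[rows] + 1L)
    csum <- numeric(dmax); cn <- numeric(dmax)
    bsum <- numeric(dmax); bn <- numeric(dmax)
    for (r in rows) {
      u <- u_all[r]; v <- v_all[r]
      L <- v - u + 1L
      for (d in seq_len(L)) {
        # pair straddling the center: bin centers sum to u + v
        i <- (u + v + 1L - d) %/% 2L
        j <- i + d
        if (i >= u && j <= v && i >= 1L && j <= N) {
          csum[d] <- csum[d] + V[i, j]
          cn[d] <- cn[d] + 1
        }
        # pairs straddling each border (boundaries at u-1 and v)
        for (p in c(u - 1L, v)) {
          i <- p - d %/% 2L
          j <- i + d
          if (i >= 1L && j <= N) {
            bsum[d] <- bsum[d] + V[i, j]
            bn[d] <- bn[d] + 1
          }
        }
      }
    }
    c_mean <- ifelse(cn > 0, csum / cn, NA_real_)
    b_mean <- ifelse(bn > 0, bsum / bn, NA_real_)
    res[[length(res) + 1L]] <- data.frame(
      category = sprintf("[%g,%g) Mb", categories$min[k] / 1e6,
                         categories$max[k] / 1e6),
      distance = seq_len(dmax) * bs,
      c_mean = c_mean, b_mean = b_mean,
      ratio = ifelse(!is.na(b_mean) & b_mean > 0, c_mean / b_mean, NA_real_))
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(category = character(0), distance = numeric(0),
                      c_mean = numeric(0), b_mean = numeric(0),
                      ratio = numeric(0))
  rownames(out) <- NULL
  out
}
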