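# Plain-text outputs: BED for domains and borders (0-based half-open),
# TSV for partitions and the mask sidecar.

#' Write domains to BED
#'
#' Five columns: chrom, start, end, name, score. For interval-community
#' tables from [extract_interval_communities()] the name encodes the scale
#' range (`scales_<first>_<last>`) and the score is `round(1000 * p_int)`;
#' plain domain tables get sequential names and score 0.
#'
#' @param domains data.frame with `chrom`, `start`, `end` and optionally
#'   `scales`/`p_int`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(domains, path) {
  name <- if ("scales" %in% names(domains)) {
    vapply(domains$scales, function(s)
      sprintf("scales_%d_%d", min(s), max(s)), character(1))
  } else sprintf("domain_%d", seq_len(nrow(domains)))
  score <- if ("p_int" %in% names(domains)) round(1000 * domains$p_int) else 0
  bed <- data.frame(chrom = domains$chrom,
                    start = format(domains$start, scientific = FALSE, trim = TRUE),
                    end = format(domains$end, scientific = FALSE, trim = TRUE),
                    name = name, score = score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write borders to BED
#'
#' Each border becomes a 1-pixel interval `[position, position +
#' bin_size)`; the score column carries the associated length.
#'
#' @param borders data.frame with `position` and `associated_length` (bp).
#' @param path output file.
#' @param chrom chromosome name.
#' @param bin_size pixel width in bp.
#' @return `path`, invisibly.
#' @export
write_borders_bed <- function(borders, path, chrom = "chr", bin_size = 1) {
  bed <- data.frame(chrom = chrom,
                    start = format(borders$position, scientific = FALSE, trim = TRUE),
                    end = format(borders$position + bin_size,
                                 scientific = FALSE, trim = TRUE),
                    name = sprintf("border_%d", seq_len(nrow(borders))),
                    score = format(borders$associated_length,
                                   scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a domain BED file
#'
#' Reads the first three (or more) BED columns and snaps interval bounds
#' to the nearest bin boundary, as needed when importing external TAD
#' calls produced at a different resolution.
#'
#' @param path BED file.
#' @param bin_size bin width in bp to snap to; 0 disables snapping.
#' @return data.frame `chrom`, `start`, `end` (plus `name`, `score` when
#'   present).
#' @export
read_domains_bed <- function(path, bin_size = 0) {
  dt <- data.table::fread(path, header = FALSE)
  out <- data.frame(chrom = as.character(dt[[1]]), start = as.numeric(dt[[2]]),
                    end = as.numeric(dt[[3]]), stringsAsFactors = FALSE)
  if (ncol(dt) >= 4L) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) out$score <- dt[[5]]
  if (bin_size > 0) {
    out$start <- round(out$start / bin_size) * bin_size
    out$end <- round(out$end / bin_size) * bin_size
    out <- out[out$end > out$start, , drop = FALSE]
  }
  out
}

#' Write the mask sidecar TSV
#'
#' One row per original bin: `original_bin` (0-based) and `kept_flag`.
#'
#' @param map a [masked_index_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_tsv <- function(map, path) {
  df <- data.frame(original_bin = seq_len(map$n_bins_total) - 1L,
                   kept_flag = as.integer(seq_len(map$n_bins_total) %in% map$kept))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one per-scale partition TSV
#'
#' Columns: `masked_index` (0-based), `original_bin` (0-based),
#' `community_id`.
#'
#' @param partition a `ScalePartition`.
#' @param map a [masked_index_map()] for the same nodes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, map, path) {
  df <- data.frame(masked_index = seq_along(partition$labels) - 1L,
                   original_bin = map$kept - 1L,
                   community_id = partition$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
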