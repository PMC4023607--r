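# Detection of runs of positionally adjacent genes coordinately up- or
# down-regulated in one line: the expression signature of a tandem
# copy-number amplification (or deletion). Adjacency is over expressed
# genes ordered by (chrom, start); runs never span chromosomes and never
# mix directions.

#' Scan for coordinated same-direction expression runs
#'
#' For every line, orders the expressed genes by chromosome and position
#' (ties broken by gene id) and reports every maximal run of at least
#' `min_run` consecutive genes with `z >= z_cut` (up) or `z <= -z_cut`
#' (down). Each call carries the member genes' z-scores and their
#' fold-changes versus the mean FPKM of the other lines.
#'
#' @param ztable A `zscore_table` over the expressed genes.
#' @param coords Data frame gene_id/chrom/start/end for (at least) the genes
#'   in `ztable`; genes missing coordinates are excluded with a warning.
#' @param fpkm The FPKM matrix the z-scores came from (for fold-changes).
#' @param min_run Minimum run length (default 3).
#' @param z_cut Z cutoff (default 2, inclusive).
#' @return List: `calls` (one row per run: line, chrom, direction, n_genes,
#'   span start/end, comma-separated gene ids) and `details` (one row per
#'   member gene with z and fold-change).
#' @export
scan_expression_runs <- function(ztable, coords, fpkm, min_run = 3, z_cut = 2) {
  z <- ztable$z
  missing_coord <- !(rownames(z) %in% coords$gene_id)
  if (any(missing_coord)) {
    .warnf("%d gene(s) without coordinates excluded from the run scan",
           sum(missing_coord))
    z <- z[!missing_coord, , drop = FALSE]
  }
  info <- coords[match(rownames(z), coords$gene_id), ]
  o <- order(info$chrom, info$start, info$gene_id)
  z <- z[o, , drop = FALSE]
  info <- info[o, ]

  calls <- list(); details <- list()
  for (line in colnames(z)) {
    for (chrom in unique(info$chrom)) {
      idx <- which(info$chrom == chrom)
      state <- ifelse(z[idx, line] >= z_cut, 1L,
                      ifelse(z[idx, line] <= -z_cut, -1L, 0L))
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values != 0L & r$lengths >= min_run)) {
        members <- idx[starts[k]:ends[k]]
        gids <- info$gene_id[members]
        other <- setdiff(colnames(fpkm), line)
        fold <- fpkm[gids, line] / rowMeans(fpkm[gids, other, drop = FALSE])
        calls[[length(calls) + 1L]] <- data.frame(
          line = line, chrom = chrom,
          direction = if (r$values[k] > 0) "up" else "down",
          n_genes = length(members),
          start = min(info$start[members]), end = max(info$end[members]),
          genes = paste(gids, collapse = ","), stringsAsFactors = FALSE)
        details[[length(details) + 1L]] <- data.frame(
          line = line, chrom = chrom, gene_id = gids,
          z = unname(z[gids, line]), fold = unname(fold),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_calls <- data.frame(line = character(0), chrom = character(0),
                            direction = character(0), n_genes = integer(0),
                            start = integer(0), end = integer(0),
                            genes = character(0))
  empty_details <- data.frame(line = character(0), chrom = character(0),
                              gene_id = character(0), z = numeric(0),
                              fold = numeric(0))
  list(calls = if (length(calls)) do.call(rbind, calls) else empty_calls,
       details = if (length(details)) do.call(rbind, details) else empty_details)
}
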