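# Landscape tracks, per-gene SNP density, functional-category enrichment
# and known-variant overlap.

#' Sliding-window feature counts along a chromosome
#'
#' Windows of `width` bases start every `step` bases from position 1; the
#' last window is truncated at the chromosome end. By default a feature is
#' assigned to a window by its (start) position, so with `step == width`
#' the window counts sum to the feature count; `mode = "overlap"` counts an
#' interval feature in every window it overlaps (for plotting parity).
#'
#' @param starts Feature start positions (1-based) on one chromosome; for
#'   point features (SNPs) the position itself.
#' @param chrom_length Chromosome length.
#' @param width Window width in bp (default 1e6).
#' @param step Step between window starts in bp (default 1e5).
#' @param mode `"start"` (default) or `"overlap"`.
#' @param ends Feature end positions (required for `mode = "overlap"`;
#'   defaults to `starts`, i.e. point features).
#' @return Data frame: window_start, window_end, count.
#' @export
window_counts <- function(starts, chrom_length, width = 1e6, step = 1e5,
                          mode = c("start", "overlap"), ends = starts) {
  mode <- match.arg(mode)
  stopifnot(chrom_length >= 1, width >= 1, step >= 1)
  ws <- seq(1, chrom_length, by = step)
  we <- pmin(ws + width - 1, chrom_length)
  count <- vapply(seq_along(ws), function(k) {
    if (mode == "start") sum(starts >= ws[k] & starts <= we[k])
    else sum(starts <= we[k] & ends >= ws[k])
  }, 0L)
  data.frame(window_start = ws, window_end = we, count = count)
}

#' Per-gene SNP count and density
#'
#' SNP density per gene as SNPs per kb of transcribed sequence, the
#' transcribed length being the union of the gene's exons over all its
#' transcripts. Genes with zero SNPs are included.
#'
#' @param effects Effect data frame (SNP rows with a gene_id are counted;
#'   one count per unique variant per gene).
#' @param models A `gene_model_set`.
#' @return Data frame: gene_id, n_snps, transcribed_kb, snps_per_kb.
#' @export
per_gene_snp_density <- function(effects, models) {
  eff <- effects[!is.na(effects$gene_id) &
                 nchar(effects$ref) == 1L & nchar(effects$alt) == 1L, ,
                 drop = FALSE]
  key <- paste(eff$gene_id, eff$chrom, eff$pos, eff$ref, eff$alt)
  eff <- eff[!duplicated(key), , drop = FALSE]
  counts <- table(eff$gene_id)
  out <- do.call(rbind, lapply(models$genes, function(g) {
    ex <- do.call(rbind, lapply(g$transcripts, function(tx) tx$exons))
    cover <- sum(.union_length(ex))
    n <- if (g$gene_id %in% names(counts)) as.integer(counts[[g$gene_id]]) else 0L
    data.frame(gene_id = g$gene_id, n_snps = n, transcribed_kb = cover / 1000,
               snps_per_kb = n / (cover / 1000), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.union_length <- function(iv) {
  if (nrow(iv) == 0) return(0L)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  total <- 0L; cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur_e + 1L) cur_e <- max(cur_e, iv[i, 2])
    else { total <- total + (cur_e - cur_s + 1L); cur_s <- iv[i, 1]; cur_e <- iv[i, 2] }
  }
  total + (cur_e - cur_s + 1L)
}

#' Functional-category enrichment of a flagged gene set
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) per category:
#' is the category overrepresented among the flagged genes relative to the
#' background? No multiple-testing correction is applied; raw p-values are
#' returned together with the 2x2 table composition.
#'
#' @param flagged_genes Character vector of flagged gene ids.
#' @param category_table Data frame with columns `gene_id`, `category`.
#' @param background Character vector of background gene ids (e.g. the
#'   expressed genes present in the category table).
#' @return Data frame: category, n_category, n_flagged_in_category,
#'   n_flagged, n_background, p_value.
#' @export
category_enrichment <- function(flagged_genes, category_table, background) {
  tab <- category_table[category_table$gene_id %in% background, , drop = FALSE]
  flagged <- intersect(flagged_genes, background)
  N <- length(unique(background))
  K <- length(flagged)
  out <- do.call(rbind, lapply(split(tab$gene_id, tab$category), function(g) {
    m <- length(unique(g))
    q <- length(intersect(g, flagged))
    # P(X >= q), X ~ Hypergeometric(m in-category, N - m out, K draws)
    p <- phyper(q - 1, m, N - m, K, lower.tail = FALSE)
    data.frame(n_category = m, n_flagged_in_category = q, p_value = p)
  }))
  data.frame(category = rownames(out), out, n_flagged = K, n_background = N,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of a call set with a known-variant list
#'
#' Matches on (chrom, pos, ref, alt).
#'
#' @param calls A call set (typically the passing variants).
#' @param known Data frame with columns chrom, pos, ref, alt.
#' @return List: `n_matched`, `n_total`, `fraction`.
#' @export
known_variant_overlap <- function(calls, known) {
  key <- .variant_key(calls)
  kkey <- paste(known$chrom, known$pos, known$ref, known$alt, sep = ":")
  n <- sum(key %in% kkey)
  list(n_matched = n, n_total = length(key),
       fraction = if (length(key)) n / length(key) else 0)
}
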