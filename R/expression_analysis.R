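# Expression-polymorphism calling on a gene x line FPKM matrix:
# expressed-gene classification, per-gene z-scores of log2 FPKM,
# presence/absence variation, fold-change outliers, cumulative abundance,
# and the premature-stop expression-ratio comparison.

#' Read a gene x line FPKM table
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `start`, `end`, then one
#' numeric column per line.
#'
#' @param path Path to the TSV.
#' @return A list: `fpkm` (numeric matrix, genes x lines, rownames = gene
#'   ids) and `coords` (data frame gene_id/chrom/start/end).
#' @export
read_fpkm <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    .stopf("FPKM table must have columns %s then one column per line",
           paste(need, collapse = ", "))
  lines <- setdiff(names(df), need)
  fpkm <- as.matrix(df[, lines, drop = FALSE])
  rownames(fpkm) <- df$gene_id
  if (any(fpkm < 0)) .stopf("negative FPKM values")
  list(fpkm = fpkm, coords = df[, need])
}

#' Drop chromosomes from an expression matrix
#'
#' Organellar (chloroplast/mitochondrial) sequences are conventionally
#' removed before nuclear expression analysis.
#'
#' @param expr A list as returned by [read_fpkm()].
#' @param drop Character vector of chromosome ids to remove.
#' @return The filtered list.
#' @export
drop_chromosomes <- function(expr, drop) {
  keep <- !(expr$coords$chrom %in% drop)
  list(fpkm = expr$fpkm[keep, , drop = FALSE], coords = expr$coords[keep, ])
}

#' Classify expressed genes
#'
#' A gene is expressed iff its mean FPKM across lines is at least
#' `mean_threshold` (inclusive) OR it has FPKM above `presence_threshold`
#' in every line.
#'
#' @param fpkm Genes x lines FPKM matrix.
#' @param mean_threshold Mean-FPKM cutoff (default 0.5).
#' @param presence_threshold Per-line presence cutoff (default 0: any
#'   non-zero FPKM counts as expressed in that line).
#' @return Named logical vector over genes.
#' @export
classify_expressed <- function(fpkm, mean_threshold = 0.5,
                               presence_threshold = 0) {
  stopifnot(ncol(fpkm) >= 1)
  rowMeans(fpkm) >= mean_threshold |
    apply(fpkm > presence_threshold, 1, all)
}

#' Per-gene z-scores of log2 FPKM
#'
#' `z = (log2(x + pseudocount) - mean) / sd` per gene across lines, with the
#' sample standard deviation (n - 1). Genes with zero variance get all-zero
#' scores.
#'
#' @param fpkm Genes x lines FPKM matrix (typically restricted to expressed
#'   genes).
#' @param pseudocount Added before the log (default 0.01, well below the
#'   0.5-FPKM expressed threshold).
#' @return An object of class `zscore_table`: list with `z` (matrix),
#'   `mean`, `sd` (per-gene, of log2 FPKM), `pseudocount`.
#' @export
expression_zscores <- function(fpkm, pseudocount = 0.01) {
  if (ncol(fpkm) < 2)
    .stopf("z-scores need at least 2 lines (sample SD undefined)")
  lg <- log2(fpkm + pseudocount)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, sd)
  z <- (lg - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  structure(list(z = z, mean = mu, sd = sdv, pseudocount = pseudocount),
            class = "zscore_table")
}

#' @export
print.zscore_table <- function(x, ...) {
  cat(sprintf("zscore_table: %d genes x %d lines (pseudocount %g)\n",
              nrow(x$z), ncol(x$z), x$pseudocount))
  invisible(x)
}

#' Call expression polymorphisms from a z-score table
#'
#' A gene is polymorphic iff any line has `|z| >= cutoff` (inclusive).
#' Per-gene, the line with the largest |z| is reported as the attributed
#' line with its direction; per-line tallies count every flagged gene-line
#' cell, and `per_line_top` attributes each polymorphic gene only to its
#' largest-|z| line (the two counting conventions both appear in published
#' summaries of this kind of screen).
#'
#' @param ztable A `zscore_table`.
#' @param cutoff Z cutoff (default 2).
#' @return List: `flags` (matrix in {-1, 0, 1}), `per_gene` (data frame:
#'   gene_id, polymorphic, max_abs_z, top_line, direction), `per_line`
#'   (up/down cell counts per line), `per_line_top` (same, top-line
#'   attribution), `n_polymorphic`.
#' @export
expression_polymorphisms <- function(ztable, cutoff = 2) {
  z <- ztable$z
  flags <- matrix(0L, nrow(z), ncol(z), dimnames = dimnames(z))
  flags[z >= cutoff] <- 1L
  flags[z <= -cutoff] <- -1L
  top_idx <- max.col(abs(z), ties.method = "first")
  max_abs <- abs(z)[cbind(seq_len(nrow(z)), top_idx)]
  polymorphic <- max_abs >= cutoff
  per_gene <- data.frame(
    gene_id = rownames(z), polymorphic = polymorphic, max_abs_z = max_abs,
    top_line = colnames(z)[top_idx],
    direction = ifelse(z[cbind(seq_len(nrow(z)), top_idx)] >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  per_line <- data.frame(
    line = colnames(z),
    up = colSums(flags == 1L),
    down = colSums(flags == -1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  top <- per_gene[per_gene$polymorphic, , drop = FALSE]
  per_line_top <- data.frame(
    line = colnames(z),
    up = vapply(colnames(z), function(l) sum(top$top_line == l & top$direction == "up"), 0L),
    down = vapply(colnames(z), function(l) sum(top$top_line == l & top$direction == "down"), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(flags = flags, per_gene = per_gene, per_line = per_line,
       per_line_top = per_line_top, n_polymorphic = sum(polymorphic))
}

#' Presence/absence variation table
#'
#' Bins genes by the number of lines in which they are present
#' (FPKM > `presence_threshold`), with mean and median FPKM over the
#' present line-values per bin. Genes present in no line are excluded, so
#' the bins partition the genes with at least one presence.
#'
#' @param fpkm Genes x lines FPKM matrix.
#' @param presence_threshold Presence cutoff (default 0).
#' @return Data frame: n_lines (1..n), n_genes, mean_fpkm, median_fpkm.
#' @export
pav_table <- function(fpkm, presence_threshold = 0) {
  present <- fpkm > presence_threshold
  k <- rowSums(present)
  n <- ncol(fpkm)
  do.call(rbind, lapply(1:n, function(b) {
    sel <- k == b
    vals <- fpkm[sel, , drop = FALSE][present[sel, , drop = FALSE]]
    data.frame(n_lines = b, n_genes = sum(sel),
               mean_fpkm = if (length(vals)) mean(vals) else NA_real_,
               median_fpkm = if (length(vals)) median(vals) else NA_real_)
  }))
}

#' Fold-change expression outliers
#'
#' Reports gene-line pairs where a line's FPKM deviates from the all-line
#' mean by at least `min_fold` in either direction, for genes whose mean
#' FPKM is at least `min_mean`. The fold is mean/value for reduced
#' expression and value/mean for increased expression; a zero line value
#' yields an infinite fold.
#'
#' @param fpkm Genes x lines FPKM matrix.
#' @param min_mean Minimum gene mean FPKM (default 10).
#' @param min_fold Minimum fold difference (default 10).
#' @return Data frame: gene_id, line, fpkm, mean_fpkm, fold, direction.
#' @export
fold_change_outliers <- function(fpkm, min_mean = 10, min_fold = 10) {
  mu <- rowMeans(fpkm)
  out <- list()
  for (g in which(mu >= min_mean)) {
    v <- fpkm[g, ]
    fold_down <- mu[g] / v
    fold_up <- v / mu[g]
    hit <- fold_down >= min_fold | fold_up >= min_fold
    for (l in which(hit)) {
      dn <- fold_down[l] >= fold_up[l]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = rownames(fpkm)[g], line = colnames(fpkm)[l],
        fpkm = v[l], mean_fpkm = mu[g],
        fold = if (dn) fold_down[l] else fold_up[l],
        direction = if (dn) "down" else "up",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(0), line = character(0),
                      fpkm = numeric(0), mean_fpkm = numeric(0),
                      fold = numeric(0), direction = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative transcript abundance ranking
#'
#' Ranks genes by their mean share of total FPKM across lines (descending)
#' and reports, for each requested share, the smallest prefix of top genes
#' whose cumulative mean share reaches it.
#'
#' @param fpkm Genes x lines FPKM matrix.
#' @param shares Numeric vector of target shares in (0, 1] (default 0.5).
#' @return List: `ranked` (data frame gene_id, mean_share, cum_share) and
#'   `prefix` (named integer vector, one entry per requested share).
#' @export
cumulative_abundance <- function(fpkm, shares = 0.5) {
  stopifnot(all(shares > 0 & shares <= 1))
  share_mat <- sweep(fpkm, 2, colSums(fpkm), "/")
  mean_share <- rowMeans(share_mat)
  mean_share <- mean_share / sum(mean_share)
  o <- order(mean_share, decreasing = TRUE)
  ranked <- data.frame(gene_id = rownames(fpkm)[o],
                       mean_share = mean_share[o],
                       cum_share = cumsum(mean_share[o]),
                       stringsAsFactors = FALSE)
  rownames(ranked) <- NULL
  prefix <- vapply(shares, function(s) {
    which(ranked$cum_share >= s - 1e-12)[1]
  }, 0L)
  names(prefix) <- paste0("share_", shares)
  list(ranked = ranked, prefix = prefix)
}

#' Expression ratio of premature-stop carriers vs non-carriers
#'
#' For every stop-gain variant, computes the ratio of the mean FPKM of the
#' gene over carrier lines (genotype het or hom_alt) to the mean over
#' non-carrier lines; returns the per-variant ratios and their mean. A mean
#' ratio near 1 indicates no systematic degradation (e.g. nonsense-mediated
#' decay) of premature-stop transcripts. Variants whose gene is absent from
#' the matrix, or lacking either carrier or non-carrier lines, are skipped.
#'
#' @param fpkm Genes x lines FPKM matrix.
#' @param effects Effect data frame from [annotate_variants()].
#' @param calls The call set (for genotypes).
#' @return List: `per_variant` (data frame) and `mean_ratio`.
#' @export
stop_gain_expression_ratio <- function(fpkm, effects, calls) {
  lines <- variant_lines(calls)
  key_calls <- .variant_key(calls)
  sel <- !is.na(effects$consequence) & effects$consequence == "stop_gain" &
    effects$gene_id %in% rownames(fpkm)
  eff <- effects[sel, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(eff))) {
    idx <- match(paste(eff$chrom[i], eff$pos[i], eff$ref[i], eff$alt[i], sep = ":"),
                 key_calls)
    geno <- vapply(lines, function(l) calls[[l]][idx], "")
    carriers <- lines[geno %in% c("het", "hom_alt")]
    others <- lines[geno == "hom_ref"]
    if (length(carriers) == 0 || length(others) == 0) next
    v <- fpkm[eff$gene_id[i], ]
    denom <- mean(v[others])
    if (denom == 0) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = eff$gene_id[i], chrom = eff$chrom[i], pos = eff$pos[i],
      n_carriers = length(carriers),
      ratio = mean(v[carriers]) / denom, stringsAsFactors = FALSE)
  }
  per_variant <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), chrom = character(0),
               pos = integer(0), n_carriers = integer(0), ratio = numeric(0))
  rownames(per_variant) <- NULL
  list(per_variant = per_variant,
       mean_ratio = if (nrow(per_variant)) mean(per_variant$ratio) else NA_real_)
}
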