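# Arithmetic on published per-line count tables. The package ships, as
# plain-text fixtures under inst/extdata, the per-line SNP/indel annotation
# class counts and acyl-lipid expression summary published for the nine-line
# soybean seed transcriptome panel (NCBI GEO accession GSE56297, reference
# Williams 82). These printed counts are inputs: the functions here
# recompute the derived ratios a reader would check by hand.

#' Read a published class-count table
#'
#' @param path TSV with a `class` column and one numeric column per line
#'   (plus optional `total`).
#' @return Data frame.
#' @export
read_count_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "txpoly")
  if (p == "") .stopf("bundled fixture %s not found", file)
  p
}

#' Derived ratios from the bundled published count tables
#'
#' Recomputes, from the packaged per-line count fixtures for the nine-line
#' soybean panel: the N/S ratio over all annotated genes and over the
#' acyl-lipid gene subset; the line-specific SNP percentage; the expressed
#' gene-model percentage; the acyl-lipid percent-expressed summary (the
#' unweighted mean of the per-category percentages, which is how the
#' published total row is composed); the mean per-line SNP count; the CDS
#' SNP percentage; and the mean transcript-nucleotide spacing between SNPs.
#'
#' @param snp_table,acyl_snp_table,acyl_expr_table,headline Optional paths
#'   overriding the bundled fixtures.
#' @return Named list of numeric values.
#' @export
published_table_ratios <- function(snp_table = .extdata("published_snp_annotation_counts.tsv"),
                                   acyl_snp_table = .extdata("published_acyl_snp_annotation_counts.tsv"),
                                   acyl_expr_table = .extdata("published_acyl_expression_summary.tsv"),
                                   headline = .extdata("published_headline_counts.tsv")) {
  snp <- read_count_table(snp_table)
  acyl <- read_count_table(acyl_snp_table)
  expr <- read_count_table(acyl_expr_table)
  hc <- read_count_table(headline)
  hval <- setNames(hc$value, hc$name)
  row_total <- function(tab, cls) tab$total[tab$class == cls]
  line_cols <- function(tab) setdiff(names(tab), c("class", "total"))

  ns_all <- ns_ratio(n_nonsyn = row_total(snp, "nonsynonymous"),
                     n_syn = row_total(snp, "synonymous"))
  ns_acyl <- ns_ratio(n_nonsyn = row_total(acyl, "nonsynonymous"),
                      n_syn = row_total(acyl, "synonymous"))
  per_line <- as.numeric(snp[snp$class == "total_in_genes", line_cols(snp)])
  pct_expressed_per_cat <- 100 * expr$expressed / expr$annotated
  pct_diffexpr_per_cat <- 100 * expr$diff_expressed / expr$expressed

  list(
    ns_ratio_all = ns_all,
    ns_ratio_acyl = ns_acyl,
    line_specific_snp_pct = 100 * hval[["line_specific_snps"]] / hval[["total_snps"]],
    expressed_gene_model_pct = 100 * hval[["expressed_gene_models"]] / hval[["annotated_gene_models"]],
    acyl_expressed_pct = mean(pct_expressed_per_cat),
    acyl_diff_expressed_pct = mean(pct_diffexpr_per_cat),
    mean_snps_per_line = mean(per_line),
    cds_snp_pct = 100 * row_total(snp, "cds") / hval[["total_snps"]],
    snp_spacing_nt = hval[["annotated_transcript_nt"]] / hval[["total_snps"]]
  )
}
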