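# Orchestration of the analysis stages over files on disk. The stages are
# plain package functions; this layer wires them together, applies the
# standard thresholds, writes the report tables and records every resolved
# threshold in a JSON run log so a threshold-dense analysis stays auditable.

#' Build a pipeline configuration
#'
#' Thresholds default to the standard values of this analysis: read depth
#' >= 5, site quality >= 50, at most 2 SNPs per 10 bp window, expressed at
#' mean FPKM >= 0.5, |Z| >= 2, runs of >= 3 adjacent genes, 1 Mb windows
#' with 0.1 Mb steps, 1000 bootstrap replicates.
#'
#' @param fasta,gff3,vcf_a,vcf_b,fpkm Input file paths.
#' @param categories Optional gene-category TSV (gene_id, category).
#' @param known_variants Optional known-variant TSV (chrom, pos, ref, alt).
#' @param out_dir Output directory.
#' @param min_depth,min_qual,max_in_window,window_bp Variant filters.
#' @param mean_threshold,pseudocount,z_cutoff,min_run Expression thresholds.
#' @param window_width,window_step Landscape windows (bp).
#' @param bootstrap_replicates,seed Phylogeny bootstrap settings.
#' @param drop_chroms Chromosomes excluded from expression analysis (e.g.
#'   organellar sequences).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, gff3, vcf_a, vcf_b, fpkm,
                            categories = NULL, known_variants = NULL,
                            out_dir = "txpoly_out",
                            min_depth = 5, min_qual = 50,
                            max_in_window = 2, window_bp = 10,
                            mean_threshold = 0.5, pseudocount = 0.01,
                            z_cutoff = 2, min_run = 3,
                            window_width = 1e6, window_step = 1e5,
                            bootstrap_replicates = 1000, seed = 1,
                            drop_chroms = character(0)) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Chains the stages: load annotation, filter variants (two-caller
#' intersection + site + cluster filters), annotate consequences, call
#' expression polymorphisms, scan for adjacent co-regulated runs, build
#' landscape tracks, assemble pseudo-molecules and estimate the NJ tree
#' with bootstrap, and write the report tables. Each stage's row counts are
#' logged; the resolved configuration is written as JSON next to the
#' outputs.
#'
#' @param config A `pipeline_config`.
#' @param stages Subset of stages to run (default all, in order).
#' @return Invisibly, a named list with every stage's in-memory result.
#' @export
run_pipeline <- function(config,
                         stages = c("filter", "annotate", "express",
                                    "clusters", "landscape", "phylo",
                                    "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(log = list())
  note <- function(...) res$log[[length(res$log) + 1L]] <<- sprintf(...)
  tsv <- function(df, name) {
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ann <- load_annotation(config$fasta, config$gff3)
  res$genome <- ann$genome; res$models <- ann$models
  note("loaded %d gene models", length(ann$models$genes))

  if ("filter" %in% stages) {
    calls_a <- normalize_indels(read_caller_vcf(config$vcf_a))
    calls_b <- normalize_indels(read_caller_vcf(config$vcf_b))
    flt <- filter_variants(calls_a, calls_b,
                           min_depth = config$min_depth,
                           min_qual = config$min_qual,
                           max_in_window = config$max_in_window,
                           window_bp = config$window_bp)
    res$filter <- flt
    tsv(flt$audit, "filter_audit.tsv")
    write_variant_vcf(flt$all, file.path(config$out_dir, "variants_flagged.vcf"))
    write_variant_vcf(flt$variants, file.path(config$out_dir, "variants_pass.vcf"))
    note("variant filter: %d of %d caller-A calls pass",
         nrow(flt$variants), nrow(calls_a))
  }

  if ("annotate" %in% stages) {
    eff <- annotate_variants(res$filter$variants, res$models, res$genome)
    res$effects <- eff
    tsv(eff, "variant_effects.tsv")
    res$snp_summary <- effect_summary(eff, res$filter$variants, type = "snp")
    res$indel_summary <- effect_summary(eff, res$filter$variants, type = "indel")
    tsv(res$snp_summary, "snp_class_counts.tsv")
    tsv(res$indel_summary, "indel_class_counts.tsv")
    note("annotated %d variant-gene pairs", nrow(eff))
  }

  expr <- read_fpkm(config$fpkm)
  if (length(config$drop_chroms)) expr <- drop_chromosomes(expr, config$drop_chroms)
  res$expr <- expr

  if ("express" %in% stages) {
    expressed <- classify_expressed(expr$fpkm, mean_threshold = config$mean_threshold)
    res$expressed <- expressed
    res$ztable <- expression_zscores(expr$fpkm[expressed, , drop = FALSE],
                                     pseudocount = config$pseudocount)
    res$polymorphisms <- expression_polymorphisms(res$ztable, cutoff = config$z_cutoff)
    res$pav <- pav_table(expr$fpkm)
    res$fold_outliers <- fold_change_outliers(expr$fpkm)
    res$abundance <- cumulative_abundance(expr$fpkm, shares = c(0.11, 0.5))
    tsv(res$polymorphisms$per_gene, "expression_polymorphisms.tsv")
    tsv(res$pav, "pav_table.tsv")
    tsv(res$fold_outliers, "fold_change_outliers.tsv")
    note("%d of %d genes expressed; %d polymorphic at |Z| >= %g",
         sum(expressed), nrow(expr$fpkm), res$polymorphisms$n_polymorphic,
         config$z_cutoff)
  }

  if ("clusters" %in% stages) {
    res$runs <- scan_expression_runs(res$ztable, expr$coords,
                                     expr$fpkm[res$expressed, , drop = FALSE],
                                     min_run = config$min_run,
                                     z_cut = config$z_cutoff)
    tsv(res$runs$calls, "expression_runs.tsv")
    tsv(res$runs$details, "expression_run_members.tsv")
    note("%d coordinated run(s) detected", nrow(res$runs$calls))
  }

  if ("landscape" %in% stages) {
    snps <- res$filter$variants[is_snp(res$filter$variants), , drop = FALSE]
    tracks <- lapply(names(res$genome), function(ch) {
      wc <- window_counts(snps$pos[snps$chrom == ch],
                          chrom_length = length(res$genome[[ch]]),
                          width = config$window_width, step = config$window_step)
      cbind(chrom = ch, wc)
    })
    res$snp_track <- do.call(rbind, tracks)
    tsv(res$snp_track, "snp_window_track.tsv")
    res$snp_density <- per_gene_snp_density(res$effects, res$models)
    tsv(res$snp_density, "per_gene_snp_density.tsv")
  }

  if ("phylo" %in% stages) {
    gm <- snp_genotype_matrix(res$filter$variants)
    res$spectrum <- shared_snp_spectrum(gm$geno)
    pm <- build_pseudomolecules(gm$geno, gm$info)
    res$pseudomolecules <- pm
    writeLines(paste0(">", names(pm$seqs), "\n", pm$seqs),
               file.path(config$out_dir, "pseudomolecules.fa"))
    bs <- bootstrap_support(pm$seqs, replicates = config$bootstrap_replicates,
                            seed = config$seed)
    res$tree <- bs$tree
    ape::write.tree(bs$tree, file.path(config$out_dir, "nj_tree.nwk"))
    note("phylogeny from %d SNP columns, %d bootstrap replicates",
         nchar(pm$seqs[[1]]), config$bootstrap_replicates)
  }

  if ("report" %in% stages) {
    if (!is.null(config$categories)) {
      cat_tab <- read.delim(config$categories, stringsAsFactors = FALSE)
      flagged <- res$polymorphisms$per_gene$gene_id[res$polymorphisms$per_gene$polymorphic]
      background <- rownames(res$ztable$z)
      res$enrichment <- category_enrichment(flagged, cat_tab, background)
      tsv(res$enrichment, "category_enrichment.tsv")
    }
    if (!is.null(config$known_variants)) {
      known <- read.delim(config$known_variants, stringsAsFactors = FALSE)
      res$known_overlap <- known_variant_overlap(res$filter$variants, known)
    }
    res$stop_gain_ratio <- stop_gain_expression_ratio(expr$fpkm, res$effects,
                                                      res$filter$variants)
  }

  resolved <- config
  class(resolved) <- NULL
  resolved <- resolved[!vapply(resolved, is.null, TRUE)]
  jsonlite::write_json(c(resolved, list(log = unlist(res$log))),
                       file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
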