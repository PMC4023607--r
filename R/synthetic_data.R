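# Seeded synthetic study generator. Emulates the structure of a nine-line
# seed-transcriptome panel: diploid inbred lines related by a known tree,
# gene models on a few chromosomes, SNP/indel calls of every consequence
# class from two noisy callers, lognormal FPKM with planted line-specific
# outliers, one planted amplified multi-gene cluster, and planted
# presence/absence genes. Every planted signal is recorded in a
# ground-truth manifest so each pipeline stage can be checked exactly.
#
# Mutations are placed on branches of the true tree (infinite-sites: each
# variant is one edge bipartition), so the genotype matrix admits a perfect
# phylogeny equal to the true tree. Variants are kept >= 11 bp apart except
# for deliberately planted cluster-window decoys, so the cluster filter's
# effect equals exactly the decoy set.

.PLANTED_SNP_CLASSES <- c("synonymous", "nonsynonymous", "stop_gain",
                          "stop_loss", "start_loss", "splice_site",
                          "utr_variant", "intron_variant")
.PLANTED_INDEL_CLASSES <- c("frameshift1", "frameshift2", "inframe_indel",
                            "stoploss_indel")

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: nine
#' lines, two ~0.5 Mb chromosomes carrying 200 gene models, one variant per
#' kb, read depth around 16, and expression noise (sigma = 0.3 on log2
#' FPKM) against which a planted one-line shift of delta = 3 log2 units is
#' called with near certainty at |Z| >= 2.
#'
#' @param seed Integer seed (mandatory: every output is reproducible).
#' @param n_lines Number of lines (default 9).
#' @param n_chroms,chrom_length,n_genes Genome shape.
#' @param snp_rate Background variants per bp (default 0.001).
#' @param indel_fraction Fraction of background variants that are 1-2 bp
#'   indels (default 0.03, the approximate published indel share).
#' @param het_fraction,missing_fraction Per-cell rates of heterozygous and
#'   missing genotype injection (background variants only).
#' @param fn_rate,fp_rate Per-caller false-negative / false-positive rates
#'   (background variants only; planted exemplars are always in both).
#' @param n_per_class Planted exemplars per consequence class (default 2).
#' @param expr_log2_mean,expr_log2_sd Gene baseline log2-FPKM distribution.
#' @param noise_sd Per-line log2 noise (default 0.3).
#' @param n_outliers,outlier_delta Planted one-line expression outliers.
#' @param cluster_len,cluster_folds Planted amplified gene cluster (one
#'   line; folds default to 15.5/9.6/8.0/9.0, the classic tandem-CNV
#'   signature).
#' @param n_pav Planted presence/absence genes.
#' @param stop_gain_expression_factor Multiplier applied to carrier lines of
#'   planted stop-gain variants (1 = no nonsense-mediated-decay effect).
#' @param n_cluster_decoys Planted 3-SNPs-in-10-bp window sets (removed by
#'   the cluster filter).
#' @param n_depth_decoys,n_qual_decoys Planted consensus calls failing the
#'   depth / quality site filters.
#' @param plant_enrichment Bias planted outlier genes into the first
#'   functional category (for the enrichment test).
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed,
                              n_lines = 9L,
                              n_chroms = 2L,
                              chrom_length = 1000000L,
                              n_genes = 200L,
                              snp_rate = 0.0025,
                              indel_fraction = 0.03,
                              het_fraction = 0.03,
                              missing_fraction = 0.01,
                              fn_rate = 0.03,
                              fp_rate = 0.02,
                              n_per_class = 2L,
                              expr_log2_mean = 3,
                              expr_log2_sd = 2,
                              noise_sd = 0.3,
                              n_outliers = 40L,
                              outlier_delta = 3,
                              cluster_len = 4L,
                              cluster_folds = c(15.5, 9.6, 8.0, 9.0),
                              n_pav = 30L,
                              stop_gain_expression_factor = 1,
                              n_cluster_decoys = 1L,
                              n_depth_decoys = 2L,
                              n_qual_decoys = 2L,
                              plant_enrichment = TRUE) {
  if (missing(seed)) .stopf("a seed is mandatory for reproducibility")
  rates <- c(snp_rate, indel_fraction, het_fraction, missing_fraction,
             fn_rate, fp_rate)
  if (any(rates < 0 | rates > 1)) .stopf("all rates must lie in [0, 1]")
  cfg <- list(seed = as.integer(seed), n_lines = as.integer(n_lines),
              n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), snp_rate = snp_rate,
              indel_fraction = indel_fraction, het_fraction = het_fraction,
              missing_fraction = missing_fraction, fn_rate = fn_rate,
              fp_rate = fp_rate, n_per_class = as.integer(n_per_class),
              expr_log2_mean = expr_log2_mean, expr_log2_sd = expr_log2_sd,
              noise_sd = noise_sd, n_outliers = as.integer(n_outliers),
              outlier_delta = outlier_delta,
              cluster_len = as.integer(cluster_len),
              cluster_folds = rep_len(cluster_folds, cluster_len),
              n_pav = as.integer(n_pav),
              stop_gain_expression_factor = stop_gain_expression_factor,
              n_cluster_decoys = as.integer(n_cluster_decoys),
              n_depth_decoys = as.integer(n_depth_decoys),
              n_qual_decoys = as.integer(n_qual_decoys),
              plant_enrichment = isTRUE(plant_enrichment))
  if (cfg$n_lines < 4) .stopf("need at least 4 lines for a phylogeny")
  n_planted_genes <- cfg$n_per_class *
    (length(.PLANTED_SNP_CLASSES) + length(.PLANTED_INDEL_CLASSES)) + 1L
  if (n_planted_genes + cfg$cluster_len + cfg$n_pav + cfg$n_outliers > cfg$n_genes)
    .stopf("config unrealizable: %d genes cannot host %d planted features",
           cfg$n_genes,
           n_planted_genes + cfg$cluster_len + cfg$n_pav + cfg$n_outliers)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic study
#'
#' Writes reference FASTA, GFF3 gene models, two caller VCFs, an FPKM table,
#' a gene-category table and a JSON ground-truth manifest into `out_dir`.
#' Identical seeds give byte-identical outputs.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `paths` (named file paths), `manifest`
#'   (ground truth, see the JSON for its fields), `genome` and `models`
#'   (the loaded annotation, round-tripped through the package readers).
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  lines <- sprintf("line%02d", seq_len(config$n_lines))
  chroms <- sprintf("chr%02d", seq_len(config$n_chroms))

  ## true tree -------------------------------------------------------------
  tree <- ape::rtree(config$n_lines, rooted = FALSE, br = NULL)
  tree$tip.label <- lines[as.integer(sub("^t", "", tree$tip.label))]
  tree$edge.length <- runif(nrow(tree$edge), 0.5, 1.5)
  edge_tips <- .edge_bipartitions(tree)

  ## genome and genes ------------------------------------------------------
  chrom_seq <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, "")
  genes <- list()
  per_chrom <- .split_counts(config$n_genes, config$n_chroms)
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    cursor <- sample(200:600, 1)
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      gene_id <- sprintf("g%04d", gi)
      # the first gene is the desaturase-style fixture: plus strand,
      # 150 codons, codon 77 forced to GAC (Asp)
      fixture <- gi == 1L
      g <- .build_gene(gene_id, chroms[ci], cursor,
                       strand = if (fixture) "+" else sample(c("+", "-"), 1),
                       n_codons = if (fixture) 150L else sample(60:300, 1),
                       force_codon = if (fixture) list(idx = 77L, codon = "GAC") else NULL)
      if (cursor + g$span_len - 1L > config$chrom_length - 600L) break
      chrom_seq[ci] <- paste0(substr(chrom_seq[ci], 1, cursor - 1L), g$seq,
                              substr(chrom_seq[ci], cursor + g$span_len,
                                     config$chrom_length))
      genes[[gene_id]] <- g
      cursor <- cursor + g$span_len + sample(200:800, 1)
    }
  }
  if (length(genes) < config$n_genes)
    .stopf("chromosomes too short for %d genes; increase chrom_length", config$n_genes)
  gene_ids <- names(genes)

  ## variant planting ------------------------------------------------------
  used <- lapply(setNames(chroms, chroms), function(x) integer(0))
  reserve <- function(chrom, pos, gap = 11L) {
    if (any(abs(used[[chrom]] - pos) < gap)) return(FALSE)
    used[[chrom]] <<- c(used[[chrom]], pos)
    TRUE
  }
  base_at <- function(chrom, pos, len = 1L) substr(chrom_seq[chrom], pos, pos + len - 1L)

  pick_edge_carriers <- function() {
    e <- sample.int(length(edge_tips), 1, prob = tree$edge.length)
    side <- edge_tips[[e]]
    if (runif(1) < 0.5) side else setdiff(lines, side)
  }

  variants <- list()
  add_variant <- function(chrom, pos, ref, alt, type, class, gene_id, codon_index,
                          carriers, origin, in_a = TRUE, in_b = TRUE) {
    variants[[length(variants) + 1L]] <<- list(
      chrom = chrom, pos = pos, ref = ref, alt = alt, type = type,
      class = class, gene_id = gene_id, codon_index = codon_index,
      carriers = carriers, origin = origin, in_a = in_a, in_b = in_b)
  }

  # genes reserved for planted consequence exemplars (one exemplar per gene)
  n_exemplars <- config$n_per_class *
    (length(.PLANTED_SNP_CLASSES) + length(.PLANTED_INDEL_CLASSES))
  exemplar_genes <- sample(gene_ids[-1], n_exemplars)
  ei <- 0L
  for (cls in .PLANTED_SNP_CLASSES) {
    for (r in seq_len(config$n_per_class)) {
      ei <- ei + 1L
      g <- genes[[exemplar_genes[ei]]]
      p <- .plant_snp_of_class(g, cls, chrom_seq[g$chrom])
      if (is.null(p) || !reserve(g$chrom, p$pos)) { # fall back to another gene
        repeat {
          alt_gene <- genes[[sample(setdiff(gene_ids[-1], exemplar_genes), 1)]]
          p <- .plant_snp_of_class(alt_gene, cls, chrom_seq[alt_gene$chrom])
          if (!is.null(p) && reserve(alt_gene$chrom, p$pos)) { g <- alt_gene; break }
        }
      }
      add_variant(g$chrom, p$pos, p$ref, p$alt, "snp", cls, g$gene_id,
                  p$codon_index, pick_edge_carriers(), "planted_class")
    }
  }
  for (cls in .PLANTED_INDEL_CLASSES) {
    for (r in seq_len(config$n_per_class)) {
      ei <- ei + 1L
      g <- genes[[exemplar_genes[ei]]]
      p <- .plant_indel_of_class(g, cls, chrom_seq[g$chrom])
      if (is.null(p) || !reserve(g$chrom, p$pos)) {
        repeat {
          alt_gene <- genes[[sample(setdiff(gene_ids[-1], exemplar_genes), 1)]]
          p <- .plant_indel_of_class(alt_gene, cls, chrom_seq[alt_gene$chrom])
          if (!is.null(p) && reserve(alt_gene$chrom, p$pos)) { g <- alt_gene; break }
        }
      }
      add_variant(g$chrom, p$pos, p$ref, p$alt, p$type, p$class, g$gene_id,
                  p$codon_index, pick_edge_carriers(), "planted_class")
    }
  }

  # desaturase fixture: codon 77 GAC -> AAC (Asp -> Asn), one carrier line
  fab <- genes[[1]]
  fab_gpos <- fab$cds_gpos[(77L - 1L) * 3L + 1L]
  stopifnot(base_at(fab$chrom, fab_gpos) == "G", reserve(fab$chrom, fab_gpos))
  fab_line <- sample(lines, 1)
  add_variant(fab$chrom, fab_gpos, "G", "A", "snp", "nonsynonymous",
              fab$gene_id, 77L, fab_line, "fab2c_like")
  fab2c_manifest <- list(gene_id = fab$gene_id, chrom = fab$chrom,
                         pos = fab_gpos, codon_index = 77L,
                         ref_codon = "GAC", alt_codon = "AAC",
                         ref_aa = "D", alt_aa = "N", carrier = fab_line)

  # cluster-window decoys: 3 SNPs spanning exactly 10 bp, intergenic
  for (d in seq_len(config$n_cluster_decoys)) {
    repeat {
      ch <- sample(chroms, 1)
      p0 <- sample(seq(50L, config$chrom_length - 50L), 1)
      if (.is_intergenic(p0, p0 + 9L, genes, ch) &&
          !any(abs(used[[ch]] - p0) < 25L)) break
    }
    for (p in c(p0, p0 + 4L, p0 + 9L)) {
      stopifnot(reserve(ch, p, gap = 1L))
      ref <- base_at(ch, p)
      add_variant(ch, p, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                  "snp", NA_character_, NA_character_, NA_integer_,
                  pick_edge_carriers(), "cluster_decoy")
    }
  }

  # site-filter decoys (consensus calls failing depth or qual in both callers)
  for (origin in c(rep("depth_decoy", config$n_depth_decoys),
                   rep("qual_decoy", config$n_qual_decoys))) {
    repeat {
      ch <- sample(chroms, 1)
      p <- sample(seq(50L, config$chrom_length - 50L), 1)
      if (reserve(ch, p)) break
    }
    ref <- base_at(ch, p)
    add_variant(ch, p, ref, sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                "snp", NA_character_, NA_character_, NA_integer_,
                pick_edge_carriers(), origin)
  }

  # background variants (tree-placed; 5% carried by all lines, i.e. the
  # reference holds the minor allele)
  n_bg <- max(0L, round(config$snp_rate * config$n_chroms * config$chrom_length) -
                length(variants))
  for (b in seq_len(n_bg)) {
    repeat {
      ch <- sample(chroms, 1)
      p <- sample(seq(50L, config$chrom_length - 50L), 1)
      if (reserve(ch, p)) break
    }
    carriers <- if (runif(1) < 0.05) lines else pick_edge_carriers()
    if (runif(1) < config$indel_fraction) {
      size <- sample(1:2, 1)
      anchor <- base_at(ch, p)
      if (runif(1) < 0.5) {  # insertion
        ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                     collapse = "")
        add_variant(ch, p, anchor, paste0(anchor, ins), "ins", NA_character_,
                    NA_character_, NA_integer_, carriers, "background")
      } else {
        ref <- base_at(ch, p, size + 1L)
        add_variant(ch, p, ref, anchor, "del", NA_character_,
                    NA_character_, NA_integer_, carriers, "background")
      }
    } else {
      ref <- base_at(ch, p)
      alt <- .mutate_base(ref)
      add_variant(ch, p, ref, alt, "snp", NA_character_, NA_character_,
                  NA_integer_, carriers, "background")
    }
  }

  truth <- do.call(rbind, lapply(variants, function(v) {
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               type = v$type, class = v$class, gene_id = v$gene_id,
               codon_index = v$codon_index,
               carriers = paste(v$carriers, collapse = ","),
               origin = v$origin, stringsAsFactors = FALSE)
  }))
  o <- order(truth$chrom, truth$pos)
  truth <- truth[o, ]
  variants <- variants[o]
  rownames(truth) <- NULL

  ## genotypes with het/missing injection (background only) ----------------
  geno <- matrix("hom_ref", nrow(truth), config$n_lines,
                 dimnames = list(NULL, lines))
  for (i in seq_len(nrow(truth))) {
    carr <- variants[[i]]$carriers
    geno[i, carr] <- "hom_alt"
    if (truth$origin[i] == "background") {
      het <- carr[runif(length(carr)) < config$het_fraction]
      geno[i, het] <- "het"
      miss <- lines[runif(config$n_lines) < config$missing_fraction]
      geno[i, miss] <- "missing"
    }
  }

  ## caller call sets -------------------------------------------------------
  n_v <- nrow(truth)
  qual <- round(runif(n_v, 60, 900))
  depth <- 5L + rpois(n_v, 11)
  qual[truth$origin == "qual_decoy"] <- sample(10:49, sum(truth$origin == "qual_decoy"),
                                               replace = TRUE)
  depth[truth$origin == "depth_decoy"] <- sample(1:4, sum(truth$origin == "depth_decoy"),
                                                 replace = TRUE)
  bg <- truth$origin == "background"
  in_a <- !(bg & runif(n_v) < config$fn_rate)
  in_b <- !(bg & runif(n_v) < config$fn_rate)

  make_calls <- function(sel, qual_jitter) {
    df <- truth[sel, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    df$qual <- pmax(50, qual[sel] + qual_jitter[sel])
    df$qual[truth$origin[sel] == "qual_decoy"] <- qual[sel][truth$origin[sel] == "qual_decoy"]
    df$depth <- depth[sel]
    for (l in lines) df[[l]] <- geno[sel, l]
    df
  }
  calls_a <- make_calls(in_a, rep(0L, n_v))
  calls_b <- make_calls(in_b, round(rnorm(n_v, 0, 20)))

  # per-caller false positives at novel positions, one random carrier line
  add_fp <- function(df, n_fp) {
    for (f in seq_len(n_fp)) {
      repeat {
        ch <- sample(chroms, 1)
        p <- sample(seq(50L, config$chrom_length - 50L), 1)
        if (reserve(ch, p)) break
      }
      ref <- base_at(ch, p)
      row <- data.frame(chrom = ch, pos = p, ref = ref,
                        alt = .mutate_base(ref), qual = round(runif(1, 60, 900)),
                        depth = 5L + rpois(1, 11), stringsAsFactors = FALSE)
      g <- setNames(rep("hom_ref", config$n_lines), lines)
      g[sample(lines, 1)] <- "hom_alt"
      for (l in lines) row[[l]] <- g[[l]]
      df <- rbind(df, row)
    }
    df
  }
  n_fp <- round(config$fp_rate * max(1L, sum(bg)))
  calls_a <- add_fp(calls_a, n_fp)
  calls_b <- add_fp(calls_b, n_fp)
  calls_a <- calls_a[order(calls_a$chrom, calls_a$pos), ]
  calls_b <- calls_b[order(calls_b$chrom, calls_b$pos), ]
  calls_a <- variant_calls(calls_a, lines)
  calls_b <- variant_calls(calls_b, lines)

  ## expression ------------------------------------------------------------
  n_g <- length(gene_ids)
  baseline <- rnorm(n_g, config$expr_log2_mean, config$expr_log2_sd)
  names(baseline) <- gene_ids

  # planted amplified cluster: consecutive (by position) genes on one chrom
  coords <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end, stringsAsFactors = FALSE)
  }))
  coords <- coords[order(coords$chrom, coords$start), ]
  rownames(coords) <- NULL
  chrom_of <- table(coords$chrom)
  big_ch <- names(chrom_of)[which.max(chrom_of)]
  ch_genes <- coords$gene_id[coords$chrom == big_ch]
  start_idx <- sample(2:(length(ch_genes) - config$cluster_len), 1)
  cluster_genes <- ch_genes[start_idx:(start_idx + config$cluster_len - 1L)]
  cluster_line <- sample(lines, 1)
  baseline[cluster_genes] <- pmax(baseline[cluster_genes], 2)

  # planted feature sets are disjoint (consequence exemplars, cluster, PAV,
  # outliers) so each planted signal is measurable in isolation
  taken <- c(cluster_genes, fab$gene_id, exemplar_genes)
  pav_genes <- sample(setdiff(gene_ids, taken), config$n_pav)
  taken <- c(taken, pav_genes)
  outlier_genes <- sample(setdiff(gene_ids, taken), config$n_outliers)
  baseline[outlier_genes] <- pmax(baseline[outlier_genes], 1)

  log2fpkm <- matrix(baseline, n_g, config$n_lines,
                     dimnames = list(gene_ids, lines)) +
    matrix(rnorm(n_g * config$n_lines, 0, config$noise_sd), n_g, config$n_lines)
  outlier_line <- sample(lines, config$n_outliers, replace = TRUE)
  outlier_dir <- sample(c("up", "down"), config$n_outliers, replace = TRUE)
  for (k in seq_len(config$n_outliers)) {
    shift <- if (outlier_dir[k] == "up") config$outlier_delta else -config$outlier_delta
    log2fpkm[outlier_genes[k], outlier_line[k]] <-
      log2fpkm[outlier_genes[k], outlier_line[k]] + shift
  }
  log2fpkm[cluster_genes, cluster_line] <-
    log2fpkm[cluster_genes, cluster_line] + log2(config$cluster_folds)

  if (config$stop_gain_expression_factor != 1) {
    sg <- truth[!is.na(truth$class) & truth$class == "stop_gain", , drop = FALSE]
    for (i in seq_len(nrow(sg))) {
      carr <- strsplit(sg$carriers[i], ",")[[1]]
      log2fpkm[sg$gene_id[i], carr] <- log2fpkm[sg$gene_id[i], carr] +
        log2(config$stop_gain_expression_factor)
    }
  }
  fpkm <- round(2^log2fpkm, 4)
  pav_present <- lapply(pav_genes, function(g) sample(lines, sample(1:(config$n_lines - 1L), 1)))
  names(pav_present) <- pav_genes
  for (g in pav_genes) fpkm[g, setdiff(lines, pav_present[[g]])] <- 0

  ## categories ------------------------------------------------------------
  cats <- c("synthesis_membrane_lipids_plastids", "synthesis_fatty_acids",
            "oil_storage", "lipid_signaling", "lipid_degradation",
            "wax_cutin", "mitochondrial_lipids", "endomembrane_lipids",
            "miscellaneous")
  category <- sample(cats, n_g, replace = TRUE)
  names(category) <- gene_ids
  if (config$plant_enrichment) {
    biased <- runif(config$n_outliers) < 0.6
    category[outlier_genes[biased]] <- cats[1]
  }

  ## write files -----------------------------------------------------------
  paths <- list(
    fasta = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    vcf_a = file.path(out_dir, "caller_A.vcf"),
    vcf_b = file.path(out_dir, "caller_B.vcf"),
    fpkm = file.path(out_dir, "fpkm.tsv"),
    categories = file.path(out_dir, "categories.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  dna <- Biostrings::DNAStringSet(chrom_seq)
  names(dna) <- chroms
  Biostrings::writeXStringSet(dna, paths$fasta, width = 70L)
  .write_gff3(genes, paths$gff3)
  write_variant_vcf(calls_a, paths$vcf_a, source_tag = "sim_caller_A")
  write_variant_vcf(calls_b, paths$vcf_b, source_tag = "sim_caller_B")
  fpkm_df <- data.frame(coords[match(gene_ids, coords$gene_id), ],
                        fpkm[gene_ids, , drop = FALSE],
                        check.names = FALSE, stringsAsFactors = FALSE)
  write.table(fpkm_df, paths$fpkm, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = gene_ids, category = unname(category)),
              paths$categories, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed, lines = lines,
    tree_newick = ape::write.tree(tree),
    variants = truth,
    fab2c_like = fab2c_manifest,
    outliers = data.frame(gene_id = outlier_genes, line = outlier_line,
                          direction = outlier_dir, stringsAsFactors = FALSE),
    cluster = list(line = cluster_line, chrom = big_ch,
                   gene_ids = cluster_genes, folds = config$cluster_folds),
    pav = data.frame(gene_id = pav_genes,
                     present_lines = vapply(pav_present, paste, "", collapse = ","),
                     stringsAsFactors = FALSE),
    proteins = vapply(genes, function(g) g$protein, ""),
    gene_structures = lapply(genes, function(g) {
      list(chrom = g$chrom, strand = g$strand, start = g$start, end = g$end,
           n_exons = nrow(g$exons))
    })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ann <- load_annotation(paths$fasta, paths$gff3)
  invisible(list(paths = paths, manifest = manifest,
                 genome = ann$genome, models = ann$models,
                 calls_a = calls_a, calls_b = calls_b, tree = tree))
}

## ---- internals ----------------------------------------------------------

.split_counts <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  if (n %% k) out[seq_len(n %% k)] <- out[seq_len(n %% k)] + 1L
  out
}

.mutate_base <- function(ref) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (runif(1) < 2 / 3) transition[[ref]]
  else sample(setdiff(c("A", "C", "G", "T"), c(ref, transition[[ref]])), 1)
}

# tips on the child side of every edge
.edge_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) return(tree$tip.label[child])
    # collect descendant tips below the child node
    stack <- child
    tips <- integer(0)
    while (length(stack)) {
      nd <- stack[1]; stack <- stack[-1]
      kids <- tree$edge[tree$edge[, 1] == nd, 2]
      tips <- c(tips, kids[kids <= n_tip])
      stack <- c(stack, kids[kids > n_tip])
    }
    tree$tip.label[tips]
  })
}

# Build one gene in local plus-orientation, then mirror for minus strand.
# Returns genomic exon/cds intervals (ascending), the gene-region sequence
# to splice into the chromosome, the protein, and the genomic positions of
# the spliced CDS in transcript order.
.build_gene <- function(gene_id, chrom, g0, strand, n_codons,
                        force_codon = NULL) {
  utr5 <- sample(30:80, 1)
  utr3 <- sample(50:150, 1)
  stops <- c("TAA", "TAG", "TGA")
  codons <- .sample_codons(n_codons - 2L)
  if (!is.null(force_codon)) codons[force_codon$idx - 1L] <- force_codon$codon
  orf <- paste0("ATG", paste(codons, collapse = ""), sample(stops, 1))
  mrna <- paste0(.random_seq(utr5), orf, .random_seq(utr3))
  L <- nchar(mrna)
  n_exons <- sample(1:4, 1)
  splits <- if (n_exons > 1) {
    s <- sort(sample(seq(10L, L - 10L, by = 1L), n_exons - 1L))
    while (any(diff(c(0L, s, L)) < 10L)) {
      s <- sort(sample(seq(10L, L - 10L, by = 1L), n_exons - 1L))
    }
    s
  } else integer(0)
  exon_m <- cbind(c(1L, splits + 1L), c(splits, L))  # mRNA coordinates
  introns <- sample(60:200, n_exons - 1L, replace = TRUE)

  # local (plus-layout) genomic intervals
  local_exons <- matrix(0L, n_exons, 2)
  seq_parts <- character(0)
  cursor <- 1L
  for (i in seq_len(n_exons)) {
    w <- exon_m[i, 2] - exon_m[i, 1] + 1L
    local_exons[i, ] <- c(cursor, cursor + w - 1L)
    seq_parts <- c(seq_parts, substr(mrna, exon_m[i, 1], exon_m[i, 2]))
    cursor <- cursor + w
    if (i < n_exons) {
      seq_parts <- c(seq_parts, .random_seq(introns[i]))
      cursor <- cursor + introns[i]
    }
  }
  gene_seq <- paste(seq_parts, collapse = "")
  Lg <- nchar(gene_seq)
  cds_m <- c(utr5 + 1L, utr5 + 3L * n_codons)  # mRNA range of the ORF
  local_cds <- .clip_to_exons(cds_m, exon_m, local_exons)

  if (strand == "-") {
    gene_seq <- .revcomp(gene_seq)
    mirror <- function(m) {
      mm <- cbind(Lg - m[, 2] + 1L, Lg - m[, 1] + 1L)
      mm[order(mm[, 1]), , drop = FALSE]
    }
    local_exons <- mirror(local_exons)
    local_cds <- mirror(local_cds)
  }
  exons <- local_exons + g0 - 1L
  cds <- local_cds + g0 - 1L
  cds_gpos <- {
    p <- unlist(lapply(seq_len(nrow(cds)), function(i) cds[i, 1]:cds[i, 2]))
    if (strand == "-") rev(p) else p
  }
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       start = g0, end = g0 + Lg - 1L, span_len = Lg, seq = gene_seq,
       exons = exons, cds = cds, cds_gpos = cds_gpos,
       n_codons = n_codons, protein = translate_cds(orf),
       orf = orf)
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.sample_codons <- function(n) {
  ok <- setdiff(names(Biostrings::GENETIC_CODE),
                c("TAA", "TAG", "TGA"))
  sample(ok, n, replace = TRUE)
}

# intersect one mRNA-coordinate range with the exon pieces and map into
# local genomic coordinates
.clip_to_exons <- function(range_m, exon_m, local_exons) {
  out <- NULL
  for (i in seq_len(nrow(exon_m))) {
    s <- max(range_m[1], exon_m[i, 1])
    e <- min(range_m[2], exon_m[i, 2])
    if (s > e) next
    off <- local_exons[i, 1] - exon_m[i, 1]
    out <- rbind(out, c(s + off, e + off))
  }
  storage.mode(out) <- "integer"
  out
}

.is_intergenic <- function(p1, p2, genes, chrom) {
  for (g in genes) {
    if (g$chrom == chrom && g$start - 10L <= p2 && g$end + 10L >= p1) return(FALSE)
  }
  TRUE
}

# choose (pos, ref, alt) realizing a SNP consequence class on gene g
.plant_snp_of_class <- function(g, class, chrom_str) {
  tx_base <- function(gpos) {
    b <- substr(chrom_str, gpos, gpos)
    if (g$strand == "-") .comp_base(b) else b
  }
  to_genomic_allele <- function(b) if (g$strand == "-") .comp_base(b) else b
  n_cod <- g$n_codons
  gc <- Biostrings::GENETIC_CODE
  try_codon <- function(ci, want) {
    gpos3 <- g$cds_gpos[((ci - 1L) * 3L + 1L):(ci * 3L)]
    codon <- paste(vapply(gpos3, tx_base, ""), collapse = "")
    for (off in sample(1:3)) {
      for (nb in sample(setdiff(c("A", "C", "G", "T"), substr(codon, off, off)))) {
        alt_codon <- codon
        substr(alt_codon, off, off) <- nb
        ref_aa <- gc[[codon]]; alt_aa <- gc[[alt_codon]]
        hit <- switch(want,
          synonymous = ref_aa == alt_aa && ref_aa != "*",
          nonsynonymous = ref_aa != alt_aa && ref_aa != "*" && alt_aa != "*",
          stop_gain = ref_aa != "*" && alt_aa == "*",
          stop_loss = ref_aa == "*" && alt_aa != "*",
          start_loss = TRUE)
        if (hit)
          return(list(pos = gpos3[off], ref = substr(chrom_str, gpos3[off], gpos3[off]),
                      alt = to_genomic_allele(nb), codon_index = ci))
      }
    }
    NULL
  }
  if (class %in% c("synonymous", "nonsynonymous", "stop_gain")) {
    for (ci in sample(2:(n_cod - 1L))) {
      p <- try_codon(ci, class)
      if (!is.null(p)) return(p)
    }
    return(NULL)
  }
  if (class == "stop_loss") return(try_codon(n_cod, "stop_loss"))
  if (class == "start_loss") {
    # mutate any base of the ATG; any change leaves a non-ATG codon
    return(try_codon(1L, "start_loss"))
  }
  if (class == "splice_site") {
    if (nrow(g$exons) < 2) return(NULL)
    i <- sample(seq_len(nrow(g$exons) - 1L), 1)
    intron <- c(g$exons[i, 2] + 1L, g$exons[i + 1L, 1] - 1L)
    pos <- sample(c(intron[1], intron[1] + 1L, intron[2] - 1L, intron[2]), 1)
    ref <- substr(chrom_str, pos, pos)
    return(list(pos = pos, ref = ref,
                alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                codon_index = NA_integer_))
  }
  if (class == "utr_variant") {
    ut <- setdiff(unlist(lapply(seq_len(nrow(g$exons)), function(i) g$exons[i, 1]:g$exons[i, 2])),
                  unlist(lapply(seq_len(nrow(g$cds)), function(i) g$cds[i, 1]:g$cds[i, 2])))
    if (length(ut) == 0) return(NULL)
    pos <- sample(ut, 1)
    ref <- substr(chrom_str, pos, pos)
    return(list(pos = pos, ref = ref,
                alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                codon_index = NA_integer_))
  }
  if (class == "intron_variant") {
    if (nrow(g$exons) < 2) return(NULL)
    mids <- integer(0)
    for (i in seq_len(nrow(g$exons) - 1L)) {
      lo <- g$exons[i, 2] + 3L
      hi <- g$exons[i + 1L, 1] - 3L
      if (hi >= lo) mids <- c(mids, lo:hi)
    }
    if (length(mids) == 0) return(NULL)
    pos <- sample(mids, 1)
    ref <- substr(chrom_str, pos, pos)
    return(list(pos = pos, ref = ref,
                alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                codon_index = NA_integer_))
  }
  NULL
}

# choose an indel realizing a class on gene g (anchored VCF representation)
.plant_indel_of_class <- function(g, class, chrom_str) {
  n_cod <- g$n_codons
  stop_cds <- ((n_cod - 1L) * 3L + 1L):(n_cod * 3L)
  stop_gpos <- g$cds_gpos[stop_cds]
  cds_index_of <- function(gpos) match(gpos, g$cds_gpos)
  wide <- which(g$cds[, 2] - g$cds[, 1] + 1L >= 12L)
  if (class == "stoploss_indel") {
    lo <- min(stop_gpos); hi <- max(stop_gpos)
    if (hi - lo != 2L) return(NULL)  # stop codon split by an intron: skip gene
    p0 <- lo - 1L
    return(list(pos = p0, ref = substr(chrom_str, p0, p0 + 1L),
                alt = substr(chrom_str, p0, p0), type = "del",
                class = "stoploss_indel", codon_index = n_cod))
  }
  if (length(wide) == 0) return(NULL)
  iv <- g$cds[sample(wide, 1), ]
  # anchor p; edited bases p+1.. inside the same CDS interval, away from stop
  for (attempt in 1:20) {
    p <- sample(seq(iv[1] + 1L, iv[2] - 5L), 1)
    span <- p:(p + 4L)
    if (any(span %in% stop_gpos)) next
    ci <- (cds_index_of(if (g$strand == "-") p + 1L else p + 1L) - 1L) %/% 3L + 1L
    if (class == "frameshift1") {
      ins <- sample(c("A", "C", "G", "T"), 1)
      return(list(pos = p, ref = substr(chrom_str, p, p),
                  alt = paste0(substr(chrom_str, p, p), ins), type = "ins",
                  class = "frameshift", codon_index = NA_integer_))
    }
    if (class == "frameshift2") {
      return(list(pos = p, ref = substr(chrom_str, p, p + 2L),
                  alt = substr(chrom_str, p, p), type = "del",
                  class = "frameshift", codon_index = ci))
    }
    if (class == "inframe_indel") {
      return(list(pos = p, ref = substr(chrom_str, p, p + 3L),
                  alt = substr(chrom_str, p, p), type = "del",
                  class = "inframe_indel", codon_index = ci))
    }
  }
  NULL
}

.write_gff3 <- function(genes, path) {
  out <- c("##gff-version 3")
  for (g in genes) {
    tx_id <- paste0(g$gene_id, ".1")
    out <- c(out,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom, g$start,
              g$end, g$strand, g$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", g$chrom,
              g$start, g$end, g$strand, tx_id, g$gene_id),
      vapply(seq_len(nrow(g$exons)), function(i) {
        sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                g$chrom, g$exons[i, 1], g$exons[i, 2], g$strand, tx_id, i, tx_id)
      }, ""),
      vapply(seq_len(nrow(g$cds)), function(i) {
        sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                g$chrom, g$cds[i, 1], g$cds[i, 2], g$strand, tx_id, i, tx_id)
      }, ""))
  }
  writeLines(out, path)
}
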