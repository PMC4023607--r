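# Codon-level consequence annotation of SNPs and small indels against
# transcript models, plus the class-count summaries and N/S ratio.
#
# Class precedence for SNPs in complete CDS:
#   start_loss > stop_gain / stop_loss > nonsynonymous > synonymous.
# Classes are counted disjointly under that precedence; the N/S ratio can
# optionally fold the start/stop-affecting classes back into the
# non-synonymous count (premature stops are amino-acid-changing SNPs).
#
# Indels: an indel overlapping the annotated stop codon is `stoploss_indel`;
# otherwise a CDS indel is `frameshift` (size not a multiple of 3) or
# `inframe_indel`; then splice-site overlap, UTR, intron, intergenic.

.EFFECT_COLS <- c("chrom", "pos", "ref", "alt", "gene_id", "transcript_id",
                  "region", "consequence", "codon_index", "ref_codon",
                  "alt_codon", "ref_aa", "alt_aa")

.empty_effects <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), length(.EFFECT_COLS)),
                               .EFFECT_COLS), stringsAsFactors = FALSE)
  df$pos <- integer(0)
  df$codon_index <- integer(0)
  df
}

.effect_row <- function(variant, tx, gene_id, region, consequence,
                        codon_index = NA_integer_, ref_codon = NA_character_,
                        alt_codon = NA_character_, ref_aa = NA_character_,
                        alt_aa = NA_character_) {
  data.frame(chrom = variant$chrom, pos = as.integer(variant$pos), ref = variant$ref,
             alt = variant$alt, gene_id = gene_id,
             transcript_id = if (is.null(tx)) NA_character_ else tx$transcript_id,
             region = region, consequence = consequence,
             codon_index = as.integer(codon_index), ref_codon = ref_codon,
             alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
             stringsAsFactors = FALSE)
}

#' Annotate a SNP against one transcript
#'
#' Locates the codon index and within-codon offset in transcript orientation
#' (minus-strand alleles are complemented), mutates the codon and translates
#' both versions. The reference allele must agree with the reference genome
#' base at the position; a mismatch is a data-integrity error.
#'
#' @param variant One-row call set record (or a list with chrom, pos, ref, alt).
#' @param tx A transcript record overlapping the position.
#' @param genome A `DNAStringSet`.
#' @param gene_id Gene id recorded in the output (default `NA`).
#' @return A one-row effect data frame.
#' @export
annotate_snp <- function(variant, tx, genome, gene_id = NA_character_) {
  stopifnot(nchar(variant$ref) == 1L, nchar(variant$alt) == 1L)
  ref_base <- as.character(Biostrings::subseq(genome[[variant$chrom]],
                                              variant$pos, variant$pos))
  if (ref_base != variant$ref)
    .stopf("reference allele %s disagrees with genome base %s at %s:%d",
           variant$ref, ref_base, variant$chrom, variant$pos)
  region <- classify_position(variant$pos, tx)
  if (region == "outside")
    return(.effect_row(variant, tx, gene_id, "outside", "intergenic"))
  if (region == "splice_site")
    return(.effect_row(variant, tx, gene_id, region, "splice_site"))
  if (region %in% c("UTR5", "UTR3"))
    return(.effect_row(variant, tx, gene_id, region, "utr_variant"))
  if (region == "intron")
    return(.effect_row(variant, tx, gene_id, region, "intron_variant"))
  if (region == "noncoding_exon")
    return(.effect_row(variant, tx, gene_id, region, NA_character_))
  # region == "CDS"
  if (tx$incomplete)  # excluded from codon-level calls
    return(.effect_row(variant, tx, gene_id, region, NA_character_))

  cds_pos <- .genome_to_cds(variant$pos, tx)
  cds_seq <- attr(tx, "cached_cds")
  if (is.null(cds_seq)) cds_seq <- spliced_cds(tx, genome)
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  offset <- (cds_pos - 1L) %% 3L + 1L
  ref_allele_tx <- if (tx$strand == "-") .comp_base(variant$ref) else variant$ref
  alt_allele_tx <- if (tx$strand == "-") .comp_base(variant$alt) else variant$alt
  ref_codon <- substr(cds_seq, (codon_index - 1L) * 3L + 1L, codon_index * 3L)
  if (substr(ref_codon, offset, offset) != ref_allele_tx)
    .stopf("internal inconsistency: CDS base at %s:%d does not match genome",
           variant$chrom, variant$pos)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt_allele_tx
  ref_aa <- translate_cds(ref_codon)
  alt_aa <- translate_cds(alt_codon)

  consequence <- if (codon_index == 1L && ref_codon == "ATG" && alt_codon != "ATG") {
    "start_loss"
  } else if (alt_aa == "*" && ref_aa != "*") {
    "stop_gain"
  } else if (ref_aa == "*" && alt_aa != "*") {
    "stop_loss"
  } else if (ref_aa != alt_aa) {
    "nonsynonymous"
  } else "synonymous"

  .effect_row(variant, tx, gene_id, region, consequence, codon_index,
              ref_codon, alt_codon, ref_aa, alt_aa)
}

#' Annotate a small indel against one transcript
#'
#' Calls are expected in anchored VCF representation (shared leading base).
#' The affected genomic span is the deleted bases for deletions and the two
#' bases flanking the insertion point for insertions.
#'
#' @inheritParams annotate_snp
#' @return A one-row effect data frame. `codon_index` is the codon holding
#'   the first affected CDS base, when the indel touches a complete CDS.
#' @export
annotate_indel <- function(variant, tx, genome, gene_id = NA_character_) {
  len_r <- nchar(variant$ref); len_a <- nchar(variant$alt)
  stopifnot(len_r != len_a || len_r > 1L)
  ref_obs <- as.character(Biostrings::subseq(genome[[variant$chrom]],
                                             variant$pos,
                                             variant$pos + len_r - 1L))
  if (ref_obs != variant$ref)
    .stopf("reference allele %s disagrees with genome sequence %s at %s:%d",
           variant$ref, ref_obs, variant$chrom, variant$pos)
  size <- abs(len_r - len_a)
  affected <- if (len_r > len_a) {
    (variant$pos + len_a):(variant$pos + len_r - 1L)  # deleted bases
  } else {
    chrom_len <- length(genome[[variant$chrom]])
    unique(pmin(chrom_len, c(variant$pos, variant$pos + 1L)))
  }
  regions <- vapply(affected, classify_position, "", tx = tx)

  cds_hit <- regions == "CDS"
  codon_index <- NA_integer_
  if (any(cds_hit) && tx$coding && !tx$incomplete) {
    cds_positions <- vapply(affected[cds_hit], .genome_to_cds, 0L, tx = tx)
    first_cds <- min(cds_positions)
    codon_index <- (first_cds - 1L) %/% 3L + 1L
    n_codons <- sum(tx$cds[, 2] - tx$cds[, 1] + 1L) %/% 3L
    stop_codon_cds <- (n_codons - 1L) * 3L + 1:3
    if (any(cds_positions %in% stop_codon_cds))
      return(.effect_row(variant, tx, gene_id, "CDS", "stoploss_indel",
                         codon_index))
    cons <- if (size %% 3L != 0L) "frameshift" else "inframe_indel"
    return(.effect_row(variant, tx, gene_id, "CDS", cons, codon_index))
  }
  if (any(cds_hit))  # incomplete transcript: region only
    return(.effect_row(variant, tx, gene_id, "CDS", NA_character_))
  if (any(regions == "splice_site"))
    return(.effect_row(variant, tx, gene_id, "splice_site", "splice_site"))
  if (any(regions %in% c("UTR5", "UTR3")))
    return(.effect_row(variant, tx, gene_id,
                       regions[regions %in% c("UTR5", "UTR3")][1], "utr_variant"))
  if (any(regions == "intron"))
    return(.effect_row(variant, tx, gene_id, "intron", "intron_variant"))
  if (any(regions == "noncoding_exon"))
    return(.effect_row(variant, tx, gene_id, "noncoding_exon", NA_character_))
  .effect_row(variant, tx, gene_id, "outside", "intergenic")
}

#' Annotate a call set against all gene models
#'
#' Every variant is annotated against every transcript of every overlapping
#' gene; per gene the most severe transcript-level consequence is reported
#' (severity: start_loss > stop_gain > stop_loss > frameshift >
#' stoploss_indel > splice_site > inframe_indel > nonsynonymous > synonymous
#' > UTR > intron). Variants overlapping no gene get one `intergenic` row.
#'
#' @param calls A call set.
#' @param models A `gene_model_set`.
#' @param genome A `DNAStringSet`.
#' @return An effect data frame, one row per variant x overlapped gene.
#' @export
annotate_variants <- function(calls, models, genome) {
  if (nrow(calls) == 0) return(.empty_effects())
  # cache spliced CDS per transcript so repeated variants in one gene are cheap
  cds_cache <- new.env(parent = emptyenv())
  gene_tab <- do.call(rbind, lapply(models$genes, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end, stringsAsFactors = FALSE)
  }))
  snp <- is_snp(calls)
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, , drop = FALSE]
    span_end <- v$pos + nchar(v$ref) - 1L
    hits <- gene_tab$gene_id[gene_tab$chrom == v$chrom &
                             gene_tab$start <= span_end & gene_tab$end >= v$pos]
    if (length(hits) == 0) {
      out[[i]] <- .effect_row(v, NULL, NA_character_, "outside", "intergenic")
      next
    }
    rows <- lapply(hits, function(gid) {
      g <- models$genes[[gid]]
      tx_rows <- lapply(g$transcripts, function(tx) {
        key <- tx$transcript_id
        if (tx$coding && !tx$incomplete) {
          if (is.null(cds_cache[[key]])) cds_cache[[key]] <- spliced_cds(tx, genome)
          attr(tx, "cached_cds") <- cds_cache[[key]]
        }
        if (snp[i]) annotate_snp(v, tx, genome, gene_id = gid)
        else annotate_indel(v, tx, genome, gene_id = gid)
      })
      tx_df <- do.call(rbind, tx_rows)
      sev <- .CONSEQUENCE_SEVERITY[tx_df$consequence]
      sev[is.na(sev)] <- max(.CONSEQUENCE_SEVERITY) + 1L
      tx_df[which.min(sev), , drop = FALSE]
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize effect classes per line
#'
#' Builds the class-count table: total variants in annotated genes, exonic,
#' UTR, CDS, non-synonymous, synonymous, start-loss, stop-gain, stop-loss,
#' splice-site and intronic counts (for SNPs), or the indel analogues. A
#' variant counts for a line iff that line's genotype is `het` or `hom_alt`;
#' the `total` column counts unique variants with at least one carrier.
#'
#' @param effects Effect data frame from [annotate_variants()], restricted
#'   to rows with a `gene_id` (one row per variant x gene).
#' @param calls The call set the effects were computed from (for genotypes).
#' @param type `"snp"` or `"indel"`: which variants to tabulate.
#' @return A data frame with one row per class and one column per line plus
#'   `total`.
#' @export
effect_summary <- function(effects, calls, type = c("snp", "indel")) {
  type <- match.arg(type)
  lines <- variant_lines(calls)
  key_calls <- .variant_key(calls)
  snp_key <- key_calls[is_snp(calls)]
  eff <- effects[!is.na(effects$gene_id), , drop = FALSE]
  ekey <- paste(eff$chrom, eff$pos, eff$ref, eff$alt, sep = ":")
  keep <- if (type == "snp") ekey %in% snp_key else !(ekey %in% snp_key)
  eff <- eff[keep, , drop = FALSE]
  ekey <- ekey[keep]

  carrier <- if (nrow(eff) == 0) {
    matrix(FALSE, 0, length(lines), dimnames = list(NULL, lines))
  } else {
    m <- sapply(lines, function(l) {
      calls[[l]][match(ekey, key_calls)] %in% c("het", "hom_alt")
    })
    matrix(m, nrow = nrow(eff), dimnames = list(NULL, lines))
  }

  classes <- list(
    total_in_genes = rep(TRUE, nrow(eff)),
    exon = eff$region %in% c("CDS", "UTR5", "UTR3", "noncoding_exon"),
    utr = eff$region %in% c("UTR5", "UTR3"),
    cds = eff$region == "CDS",
    nonsynonymous = !is.na(eff$consequence) & eff$consequence == "nonsynonymous",
    synonymous = !is.na(eff$consequence) & eff$consequence == "synonymous",
    start_loss = !is.na(eff$consequence) & eff$consequence == "start_loss",
    stop_gain = !is.na(eff$consequence) & eff$consequence == "stop_gain",
    stop_loss = !is.na(eff$consequence) & eff$consequence == "stop_loss",
    frameshift = !is.na(eff$consequence) & eff$consequence == "frameshift",
    inframe_indel = !is.na(eff$consequence) & eff$consequence == "inframe_indel",
    stoploss_indel = !is.na(eff$consequence) & eff$consequence == "stoploss_indel",
    splice_site = !is.na(eff$consequence) & eff$consequence == "splice_site",
    intron = eff$region == "intron"
  )
  tab <- t(vapply(classes, function(sel) {
    per_line <- if (nrow(eff) == 0) rep(0L, length(lines)) else {
      vapply(lines, function(l) {
        length(unique(ekey[sel & carrier[, l]]))
      }, 0L)
    }
    c(per_line, total = length(unique(ekey[sel])))
  }, numeric(length(lines) + 1L)))
  out <- data.frame(class = names(classes), tab, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Non-synonymous to synonymous SNP ratio
#'
#' Ratio of non-synonymous over synonymous SNP counts over unique variants
#' in scope. With `include_stop_affecting = TRUE` the start-loss, stop-gain
#' and stop-loss classes are folded into the non-synonymous numerator (they
#' are amino-acid-changing substitutions).
#'
#' @param effects Effect data frame, or `NULL` when counts are given.
#' @param genes Optional gene-id subset.
#' @param include_stop_affecting Fold start/stop-affecting SNPs into the
#'   numerator (default `FALSE`: disjoint classes only).
#' @param n_nonsyn,n_syn Direct counts (bypass `effects`), e.g. from a
#'   published class-count table.
#' @return The ratio, or `NA` with a warning when no synonymous SNPs are in
#'   scope (ratio undefined).
#' @export
ns_ratio <- function(effects = NULL, genes = NULL,
                     include_stop_affecting = FALSE,
                     n_nonsyn = NULL, n_syn = NULL) {
  if (is.null(n_nonsyn) || is.null(n_syn)) {
    stopifnot(!is.null(effects))
    eff <- effects[nchar(effects$ref) == 1L & nchar(effects$alt) == 1L, , drop = FALSE]
    if (!is.null(genes)) eff <- eff[eff$gene_id %in% genes, , drop = FALSE]
    key <- paste(eff$chrom, eff$pos, eff$ref, eff$alt, sep = ":")
    cls_of <- function(cls) length(unique(key[!is.na(eff$consequence) &
                                              eff$consequence %in% cls]))
    n_nonsyn <- cls_of("nonsynonymous")
    if (include_stop_affecting)
      n_nonsyn <- n_nonsyn + cls_of(c("start_loss", "stop_gain", "stop_loss"))
    n_syn <- cls_of("synonymous")
  }
  if (n_syn == 0) {
    .warnf("no synonymous SNPs in scope; N/S ratio undefined")
    return(NA_real_)
  }
  n_nonsyn / n_syn
}
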