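# Independent oracles. These deliberately avoid the package's coordinate
# arithmetic: regions come from exhaustive per-base maps, translation from
# Biostrings::translate, and consequence classes from rebuilding and
# translating the full mutant CDS.

# brute-force per-base region map over the transcript span
oracle_region_map <- function(tx) {
  span <- tx$exons[1, 1]:tx$exons[nrow(tx$exons), 2]
  lab <- setNames(rep("intron", length(span)), span)
  exonic <- unlist(lapply(seq_len(nrow(tx$exons)),
                          function(i) tx$exons[i, 1]:tx$exons[i, 2]))
  # splice sites: 2 intronic bases flanking every exon gap
  if (nrow(tx$exons) > 1) {
    for (i in seq_len(nrow(tx$exons) - 1L)) {
      gap <- (tx$exons[i, 2] + 1L):(tx$exons[i + 1L, 1] - 1L)
      ss <- unique(c(head(gap, 2), tail(gap, 2)))
      lab[as.character(ss)] <- "splice_site"
    }
  }
  if (!tx$coding) {
    lab[as.character(exonic)] <- "noncoding_exon"
    return(lab)
  }
  cds <- unlist(lapply(seq_len(nrow(tx$cds)),
                       function(i) tx$cds[i, 1]:tx$cds[i, 2]))
  utr <- setdiff(exonic, cds)
  left <- utr[utr < min(cds)]
  right <- utr[utr > max(cds)]
  lab[as.character(setdiff(exonic, cds))] <- NA
  lab[as.character(cds)] <- "CDS"
  if (tx$strand == "+") {
    lab[as.character(left)] <- "UTR5"; lab[as.character(right)] <- "UTR3"
  } else {
    lab[as.character(left)] <- "UTR3"; lab[as.character(right)] <- "UTR5"
  }
  lab
}

oracle_classify <- function(pos, tx) {
  m <- oracle_region_map(tx)
  if (!as.character(pos) %in% names(m)) return("outside")
  unname(m[as.character(pos)])
}

# independent translator (seqinr); Biostrings::translate is exercised once
# on a long random sequence in the genome-model tests
oracle_translate <- function(s) {
  paste(seqinr::translate(strsplit(tolower(s), "")[[1]], ambiguous = FALSE),
        collapse = "")
}

# spliced CDS by an independent per-base walk (character vectors, chartr)
oracle_spliced_cds <- function(tx, chrom_str) {
  cds_pos <- unlist(lapply(seq_len(nrow(tx$cds)),
                           function(i) tx$cds[i, 1]:tx$cds[i, 2]))
  bases <- vapply(cds_pos, function(p) substr(chrom_str, p, p), "")
  if (tx$strand == "-") bases <- rev(chartr("ACGT", "TGCA", bases))
  paste(bases, collapse = "")
}

# reusable per-transcript context so repeated oracle calls are cheap: the
# region map, the CDS genomic-position walk and the reference protein are
# each computed once
oracle_context <- function(tx, chrom_str) {
  cds_pos <- unlist(lapply(seq_len(nrow(tx$cds)),
                           function(i) tx$cds[i, 1]:tx$cds[i, 2]))
  if (tx$strand == "-") cds_pos <- rev(cds_pos)
  ref_cds <- oracle_spliced_cds(tx, chrom_str)
  list(tx = tx, chrom_str = chrom_str, map = oracle_region_map(tx),
       cds_pos = cds_pos, ref_cds = ref_cds,
       ref_prot = oracle_translate(ref_cds))
}

oracle_classify_ctx <- function(pos, ctx) {
  if (!as.character(pos) %in% names(ctx$map)) return("outside")
  unname(ctx$map[as.character(pos)])
}

# SNP consequence by rebuilding the mutant CDS and diffing proteins
oracle_annotate_snp <- function(chrom_str, pos, ref, alt, tx, ctx = NULL) {
  if (is.null(ctx)) ctx <- oracle_context(tx, chrom_str)
  stopifnot(substr(chrom_str, pos, pos) == ref)
  region <- oracle_classify_ctx(pos, ctx)
  if (region %in% c("outside")) return(list(region = region, consequence = "intergenic"))
  if (region == "splice_site") return(list(region = region, consequence = "splice_site"))
  if (region %in% c("UTR5", "UTR3")) return(list(region = region, consequence = "utr_variant"))
  if (region == "intron") return(list(region = region, consequence = "intron_variant"))
  if (region == "noncoding_exon" || tx$incomplete)
    return(list(region = region, consequence = NA_character_))
  cds_idx0 <- match(pos, ctx$cds_pos)
  alt_tx <- if (tx$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  ref_cds <- ctx$ref_cds
  alt_cds <- ref_cds
  substr(alt_cds, cds_idx0, cds_idx0) <- alt_tx
  ref_prot <- ctx$ref_prot
  alt_prot <- oracle_translate(alt_cds)
  d <- which(strsplit(ref_prot, "")[[1]] != strsplit(alt_prot, "")[[1]])
  cds_idx <- which(strsplit(ref_cds, "")[[1]] != strsplit(alt_cds, "")[[1]])
  codon_index <- (cds_idx - 1L) %/% 3L + 1L
  cons <- if (codon_index == 1L && substr(ref_cds, 1, 3) == "ATG" &&
              substr(alt_cds, 1, 3) != "ATG") {
    "start_loss"
  } else if (length(d) == 0) {
    "synonymous"
  } else {
    ref_aa <- substr(ref_prot, d[1], d[1])
    alt_aa <- substr(alt_prot, d[1], d[1])
    if (alt_aa == "*" && ref_aa != "*") "stop_gain"
    else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
    else "nonsynonymous"
  }
  list(region = region, consequence = cons, codon_index = codon_index)
}

# indel consequence from per-base maps and the mutant CDS length
oracle_annotate_indel <- function(chrom_str, pos, ref, alt, tx, ctx = NULL) {
  if (is.null(ctx)) ctx <- oracle_context(tx, chrom_str)
  len_r <- nchar(ref); len_a <- nchar(alt)
  affected <- if (len_r > len_a) (pos + len_a):(pos + len_r - 1L)
              else c(pos, pos + 1L)
  regions <- vapply(affected, oracle_classify_ctx, "", ctx = ctx)
  size <- abs(len_r - len_a)
  cds_pos <- ctx$cds_pos
  n_cod <- length(cds_pos) %/% 3L
  stop_gpos <- cds_pos[((n_cod - 1L) * 3L + 1L):(n_cod * 3L)]
  hit_cds <- affected[regions == "CDS"]
  if (length(hit_cds) && tx$coding && !tx$incomplete) {
    if (any(hit_cds %in% stop_gpos)) return("stoploss_indel")
    return(if (size %% 3L != 0L) "frameshift" else "inframe_indel")
  }
  if (any(regions == "splice_site")) return("splice_site")
  if (any(regions %in% c("UTR5", "UTR3"))) return("utr_variant")
  if (any(regions == "intron")) return("intron_variant")
  "intergenic"
}

# brute-force site-filter predicate
oracle_site_pass <- function(calls, min_depth = 5, min_qual = 50) {
  calls$depth >= min_depth & calls$qual >= min_qual
}

# exhaustive cluster-window enumeration: a SNP fails iff some window of
# window_bp consecutive bases holds more than max_in_window SNPs incl. it
oracle_cluster_fail <- function(chrom, pos, max_in_window = 2, window_bp = 10) {
  fail <- rep(FALSE, length(pos))
  for (i in seq_along(pos)) {
    for (w0 in (pos[i] - window_bp + 1L):pos[i]) {
      inside <- which(chrom == chrom[i] & pos >= w0 & pos <= w0 + window_bp - 1L)
      if (length(inside) > max_in_window && i %in% inside) fail[inside] <- TRUE
    }
  }
  fail
}

# brute-force maximal-run enumeration for one line's ordered z vector
oracle_runs <- function(z, min_run = 3, z_cut = 2) {
  state <- ifelse(z >= z_cut, 1L, ifelse(z <= -z_cut, -1L, 0L))
  runs <- list()
  i <- 1L
  while (i <= length(state)) {
    if (state[i] != 0L) {
      j <- i
      while (j < length(state) && state[j + 1L] == state[i]) j <- j + 1L
      if (j - i + 1L >= min_run)
        runs[[length(runs) + 1L]] <- list(from = i, to = j, dir = state[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}
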