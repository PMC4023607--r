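# In-memory fixtures: handmade transcript models on tiny chromosomes, plus
# random gene fixtures drawn from the package's own generator internals.

# genome from a named list of chromosome strings
make_genome <- function(...) {
  seqs <- list(...)
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

# transcript record in the package's internal layout
make_tx <- function(id, chrom, strand, exons, cds = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1]), , drop = FALSE]
  } else {
    cds <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  cds_len <- if (nrow(cds)) sum(cds[, 2] - cds[, 1] + 1L) else 0L
  list(transcript_id = id, chrom = chrom, strand = strand, exons = exons,
       cds = cds, coding = cds_len > 0L, incomplete = cds_len > 0L && cds_len %% 3L != 0L)
}

# a random coding gene embedded in a random chromosome, via the generator's
# own gene builder; returns genome, tx record and the gene record
random_gene_fixture <- function(seed, strand = NULL, n_codons = NULL,
                                pad = 300L) {
  set.seed(seed)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  if (is.null(n_codons)) n_codons <- sample(40:120, 1)
  g <- txpoly:::.build_gene("gX", "chrT", pad + 1L, strand, n_codons)
  chrom <- paste0(txpoly:::.random_seq(pad), g$seq, txpoly:::.random_seq(pad))
  genome <- make_genome(chrT = chrom)
  tx <- make_tx("gX.1", "chrT", strand,
                exons = t(g$exons), cds = t(g$cds))
  list(genome = genome, tx = tx, gene = g, chrom = chrom)
}

# minimal call-set constructor for filter tests (no genotypes needed beyond
# two placeholder lines)
make_calls <- function(chrom, pos, ref, alt, qual = 100, depth = 20,
                       lines = c("l1", "l2"), geno = "hom_alt") {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   qual = rep_len(qual, n), depth = rep_len(depth, n),
                   stringsAsFactors = FALSE)
  for (l in lines) df[[l]] <- rep_len(geno, n)
  df <- df[order(df$chrom, df$pos), ]
  variant_calls(df, lines)
}
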