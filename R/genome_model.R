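# Reference genome and gene models
#
# External files use 1-based inclusive coordinates (GFF3/VCF convention).
# All internal interval arithmetic here also keeps 1-based closed intervals;
# per-base offsets are computed locally where needed so there is a single
# convention throughout the package.

#' Read a reference genome from FASTA
#'
#' Loads a multi-record (possibly line-wrapped) FASTA file into a
#' [Biostrings::DNAStringSet] and validates that only the five-letter
#' nucleotide alphabet (A, C, G, T, N) is present and that every chromosome
#' has a unique, non-empty sequence.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) .stopf("FASTA file not found: %s", fasta_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    .stopf("duplicate chromosome ids in %s", fasta_path)
  if (any(Biostrings::width(genome) == 0L))
    .stopf("empty sequence record in %s", fasta_path)
  freq <- Biostrings::alphabetFrequency(genome, collapse = TRUE)
  extra <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (extra > 0)
    .stopf("genome contains letters outside the A/C/G/T/N alphabet")
  genome
}

#' Load reference genome and gene models
#'
#' Reads a FASTA reference and a GFF3 annotation (gene -> mRNA -> exon/CDS,
#' linked by `ID`/`Parent` attributes) and returns the pair used by the
#' annotation engine. Transcripts whose CDS intervals fall outside their
#' exons are rejected with a warning; transcripts whose total CDS length is
#' not a multiple of 3 are loaded but flagged `incomplete` and excluded from
#' codon-level consequence calls.
#'
#' @param fasta_path Path to the reference FASTA.
#' @param gff3_path Path to the GFF3 gene models.
#' @return A list with elements `genome` (a `DNAStringSet`) and `models`
#'   (a `gene_model_set`, see [read_gene_models()]).
#' @export
load_annotation <- function(fasta_path, gff3_path) {
  genome <- read_genome(fasta_path)
  models <- read_gene_models(gff3_path)
  bad <- setdiff(unique(vapply(models$genes, `[[`, "", "chrom")), names(genome))
  if (length(bad) > 0)
    .stopf("gene models reference chromosomes absent from the FASTA: %s",
           paste(bad, collapse = ", "))
  list(genome = genome, models = models)
}

#' Read gene models from GFF3
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @return An object of class `gene_model_set`: a list with `genes` (named
#'   list of gene records, each holding chrom, strand, start/end and its
#'   transcripts with sorted exon and CDS intervals) and `by_chrom`, an index
#'   of gene ids per chromosome used for interval queries.
#' @export
read_gene_models <- function(gff3_path) {
  if (!file.exists(gff3_path)) .stopf("GFF3 file not found: %s", gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  if (!"ID" %in% names(df)) df$ID <- NA_character_
  # Parent comes back as a CharacterList; our models are single-parent
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p) == 0) NA_character_ else as.character(p[[1]]), "")
  } else rep(NA_character_, nrow(df))
  df$parent1 <- parent

  genes_df <- df[df$type == "gene", , drop = FALSE]
  mrna_df <- df[df$type == "mRNA", , drop = FALSE]
  part_df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(genes_df) == 0) .stopf("no gene features in %s", gff3_path)
  if (any(is.na(mrna_df$parent1)))
    .stopf("malformed GFF3: mRNA feature without Parent (ID %s)",
           paste(mrna_df$ID[is.na(mrna_df$parent1)], collapse = ", "))
  orphan <- !(mrna_df$parent1 %in% genes_df$ID)
  if (any(orphan))
    .stopf("malformed GFF3: mRNA Parent not a gene for %s",
           paste(mrna_df$ID[orphan], collapse = ", "))
  if (any(is.na(part_df$parent1)) || !all(part_df$parent1 %in% mrna_df$ID))
    .stopf("malformed GFF3: exon/CDS feature with missing or unknown Parent")

  genes <- list()
  for (gi in seq_len(nrow(genes_df))) {
    g <- genes_df[gi, ]
    gene_id <- g$ID
    txs <- list()
    tx_rows <- mrna_df[mrna_df$parent1 == gene_id, , drop = FALSE]
    ok <- TRUE
    for (ti in seq_len(nrow(tx_rows))) {
      t <- tx_rows[ti, ]
      parts <- part_df[part_df$parent1 == t$ID, , drop = FALSE]
      exons <- .interval_matrix(parts[parts$type == "exon", c("start", "end")])
      cds <- .interval_matrix(parts[parts$type == "CDS", c("start", "end")])
      if (nrow(exons) == 0) .stopf("transcript %s has no exons", t$ID)
      if (.intervals_overlap(exons))
        .stopf("transcript %s has overlapping exons", t$ID)
      if (!.contained_in(cds, exons)) {
        .warnf("transcript %s rejected: CDS interval outside exons; gene %s skipped",
               t$ID, gene_id)
        ok <- FALSE
        break
      }
      cds_len <- if (nrow(cds)) sum(cds[, 2] - cds[, 1] + 1L) else 0L
      txs[[t$ID]] <- list(
        transcript_id = t$ID, chrom = t$seqnames, strand = t$strand,
        exons = exons, cds = cds, coding = cds_len > 0L,
        incomplete = cds_len > 0L && cds_len %% 3L != 0L
      )
    }
    if (!ok || length(txs) == 0) next
    genes[[gene_id]] <- list(
      gene_id = gene_id, chrom = g$seqnames, strand = g$strand,
      start = g$start, end = g$end, transcripts = txs
    )
  }
  by_chrom <- if (length(genes))
    split(names(genes), vapply(genes, `[[`, "", "chrom")) else list()
  structure(list(genes = genes, by_chrom = by_chrom), class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  n_tx <- sum(vapply(x$genes, function(g) length(g$transcripts), 0L))
  cat(sprintf("gene_model_set: %d genes, %d transcripts on %d chromosome(s)\n",
              length(x$genes), n_tx, length(x$by_chrom)))
  invisible(x)
}

.interval_matrix <- function(df) {
  if (nrow(df) == 0) return(matrix(integer(0), ncol = 2,
                                   dimnames = list(NULL, c("start", "end"))))
  m <- as.matrix(df[order(df$start), , drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

.intervals_overlap <- function(m) {
  if (nrow(m) < 2) return(FALSE)
  any(m[-1, 1] <= m[-nrow(m), 2])
}

.contained_in <- function(inner, outer) {
  if (nrow(inner) == 0) return(TRUE)
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer[, 1] <= inner[i, 1] & outer[, 2] >= inner[i, 2])
  }, TRUE))
}

#' Extract the spliced coding sequence of a transcript
#'
#' Concatenates the CDS intervals in transcription order and, for
#' minus-strand transcripts, returns the reverse complement so the result
#' starts with the annotated first codon.
#'
#' @param tx A transcript record from a `gene_model_set`.
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @return A character scalar; its length is a multiple of 3.
#' @export
spliced_cds <- function(tx, genome) {
  if (!tx$coding) .stopf("transcript %s is non-coding", tx$transcript_id)
  if (tx$incomplete)
    .stopf("transcript %s has a CDS length that is not a multiple of 3; codon-level extraction refused",
           tx$transcript_id)
  chrom_seq <- genome[[tx$chrom]]
  pieces <- vapply(seq_len(nrow(tx$cds)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, tx$cds[i, 1], tx$cds[i, 2]))
  }, "")
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code; stop codons render `*` and codons
#' containing `N` render `X`. Translation does not truncate at internal
#' stops: the caller decides what a premature stop means.
#'
#' @param cds_sequence Character scalar over A/C/G/T/N, length a multiple of 3.
#' @return The amino-acid string.
#' @export
translate_cds <- function(cds_sequence) {
  n <- nchar(cds_sequence)
  if (n %% 3L != 0L) .stopf("CDS length %d is not a multiple of 3", n)
  if (n == 0L) return("")
  if (grepl("[^ACGTN]", cds_sequence))
    .stopf("CDS contains letters outside A/C/G/T/N")
  codons <- substring(cds_sequence, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # any codon containing N
  paste(aa, collapse = "")
}

#' Classify a genomic position relative to a transcript
#'
#' Returns exactly one region label for a 1-based position: `CDS`, `UTR5`,
#' `UTR3`, `intron`, `splice_site`, `noncoding_exon` or `outside`. Splice
#' sites are the first and last 2 bases of every intron (the canonical
#' donor/acceptor core) and take precedence over the plain intron label.
#' UTR sides are resolved strand-aware (5' side of transcription).
#'
#' @param pos 1-based genomic position.
#' @param tx A transcript record.
#' @param chrom_length Optional chromosome length; when given, positions
#'   outside `[1, chrom_length]` raise an error.
#' @param splice_width Number of intronic bases at each intron end treated as
#'   splice site (default 2).
#' @return A region label (character scalar).
#' @export
classify_position <- function(pos, tx, chrom_length = NULL, splice_width = 2L) {
  if (!is.null(chrom_length) && (pos < 1L || pos > chrom_length))
    .stopf("position %d outside chromosome bounds [1, %d]", pos, chrom_length)
  exons <- tx$exons
  span <- c(exons[1, 1], exons[nrow(exons), 2])
  if (pos < span[1] || pos > span[2]) return("outside")
  in_exon <- any(exons[, 1] <= pos & exons[, 2] >= pos)
  if (!in_exon) {
    # intronic: check distance to the flanking exon edges
    up_end <- max(exons[exons[, 2] < pos, 2])
    down_start <- min(exons[exons[, 1] > pos, 1])
    if (pos - up_end <= splice_width || down_start - pos <= splice_width)
      return("splice_site")
    return("intron")
  }
  if (!tx$coding) return("noncoding_exon")
  cds <- tx$cds
  if (any(cds[, 1] <= pos & cds[, 2] >= pos)) return("CDS")
  if (pos < cds[1, 1]) {
    return(if (tx$strand == "+") "UTR5" else "UTR3")
  }
  if (tx$strand == "+") "UTR3" else "UTR5"
}

# Map a genomic position to its 1-based coordinate within the spliced CDS
# (transcript orientation). NA when the position is not coding.
.genome_to_cds <- function(pos, tx) {
  pos <- as.integer(pos)
  cds <- tx$cds
  hit <- which(cds[, 1] <= pos & cds[, 2] >= pos)
  if (length(hit) == 0) return(NA_integer_)
  widths <- cds[, 2] - cds[, 1] + 1L
  before <- if (hit > 1) sum(widths[seq_len(hit - 1)]) else 0L
  fwd <- before + (pos - cds[hit, 1]) + 1L
  if (tx$strand == "+") fwd else sum(widths) - fwd + 1L
}

# Genomic positions of the spliced CDS in transcript order.
.cds_genomic_positions <- function(tx) {
  p <- unlist(lapply(seq_len(nrow(tx$cds)), function(i) tx$cds[i, 1]:tx$cds[i, 2]))
  if (tx$strand == "-") rev(p) else p
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]
}
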