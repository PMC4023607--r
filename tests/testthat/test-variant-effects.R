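# Codon-level consequence annotation against the brute-force
# mutant-CDS-translation oracle, plus class summaries and the N/S ratio.

snp_at <- function(chrom, pos, ref, alt) {
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

test_that("textbook SNP consequences are called correctly", {
  #          UTR5      CDS: ATG GAC GGC TAC TAA          UTR3
  chrom <- paste0("AAAAA", "ATGGACGGCTACTAA", "CCCCC")
  genome <- make_genome(chr1 = chrom)
  tx <- make_tx("t1", "chr1", "+", exons = c(1, 25), cds = c(6, 20))
  # GAC -> AAC at codon 2 position 1: nonsynonymous Asp -> Asn
  e <- annotate_snp(snp_at("chr1", 9, "G", "A"), tx, genome)
  expect_equal(e$consequence, "nonsynonymous")
  expect_equal(e$codon_index, 2L)
  expect_equal(c(e$ref_codon, e$alt_codon), c("GAC", "AAC"))
  expect_equal(c(e$ref_aa, e$alt_aa), c("D", "N"))
  # GGC -> GGT at codon 3 position 3: synonymous (Gly)
  e <- annotate_snp(snp_at("chr1", 14, "C", "T"), tx, genome)
  expect_equal(e$consequence, "synonymous")
  # TAC -> TAA at codon 4 position 3: stop gain
  e <- annotate_snp(snp_at("chr1", 17, "C", "A"), tx, genome)
  expect_equal(e$consequence, "stop_gain")
  # TAA -> CAA at the stop codon: stop loss
  e <- annotate_snp(snp_at("chr1", 18, "T", "C"), tx, genome)
  expect_equal(e$consequence, "stop_loss")
  # ATG -> GTG: start loss (precedence over nonsynonymous)
  e <- annotate_snp(snp_at("chr1", 6, "A", "G"), tx, genome)
  expect_equal(e$consequence, "start_loss")
  # reference mismatch is a data-integrity error naming the position
  expect_error(annotate_snp(snp_at("chr1", 9, "T", "A"), tx, genome), "chr1:9")
})

test_that("indel consequences: frameshift, in-frame, stop-overlapping", {
  chrom <- paste0("AAAAA", "ATGGACGGCTACGGATAA", "CCCCC")
  genome <- make_genome(chr1 = chrom)
  tx <- make_tx("t1", "chr1", "+", exons = c(1, 28), cds = c(6, 23))
  # 1 bp insertion inside codon 1: frameshift
  e <- annotate_indel(list(chrom = "chr1", pos = 6, ref = "A", alt = "AT"),
                      tx, genome)
  expect_equal(e$consequence, "frameshift")
  expect_equal(e$codon_index, 1L)
  # 2 bp deletion: frameshift
  e <- annotate_indel(list(chrom = "chr1", pos = 9, ref = "GAC", alt = "G"),
                      tx, genome)
  expect_equal(e$consequence, "frameshift")
  # 3 bp deletion: in-frame
  e <- annotate_indel(list(chrom = "chr1", pos = 9, ref = "GACG", alt = "G"),
                      tx, genome)
  expect_equal(e$consequence, "inframe_indel")
  # deletion touching the stop codon
  e <- annotate_indel(list(chrom = "chr1", pos = 20, ref = "AT", alt = "A"),
                      tx, genome)
  expect_equal(e$consequence, "stoploss_indel")
  # UTR insertion
  e <- annotate_indel(list(chrom = "chr1", pos = 2, ref = "A", alt = "AC"),
                      tx, genome)
  expect_equal(e$consequence, "utr_variant")
})

test_that("annotation equals the mutant-CDS-translation oracle on random variants", {
  set.seed(2024)
  got_region <- character(0); want_region <- character(0)
  got_cons <- character(0); want_cons <- character(0)
  for (seed in 1:12) {
    fx <- random_gene_fixture(seed)
    ctx <- oracle_context(fx$tx, fx$chrom)
    tx <- fx$tx
    attr(tx, "cached_cds") <- spliced_cds(tx, fx$genome)
    span <- fx$tx$exons[1, 1]:fx$tx$exons[nrow(fx$tx$exons), 2]
    pos_pool <- sample(span, min(90, length(span)))
    for (p in pos_pool) {
      ref <- substr(fx$chrom, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- annotate_snp(snp_at("chrT", p, ref, alt), tx, fx$genome)
      want <- oracle_annotate_snp(fx$chrom, p, ref, alt, fx$tx, ctx = ctx)
      got_region <- c(got_region, got$region)
      want_region <- c(want_region, want$region)
      got_cons <- c(got_cons, got$consequence)
      want_cons <- c(want_cons, want$consequence)
      if (!is.na(got$codon_index) &&
          want$consequence %in% c("nonsynonymous", "stop_gain", "stop_loss"))
        expect_identical(got$codon_index, as.integer(want$codon_index))
    }
  }
  expect_identical(got_region, want_region)
  expect_identical(got_cons, want_cons)
  expect_gte(length(got_cons), 1000L)
})

test_that("indel annotation equals the interval-overlap oracle on random indels", {
  set.seed(501)
  n_checked <- 0L
  got_cons <- character(0); want_cons <- character(0)
  for (seed in 13:20) {
    fx <- random_gene_fixture(seed)
    ctx <- oracle_context(fx$tx, fx$chrom)
    span <- (fx$tx$exons[1, 1] - 5L):(fx$tx$exons[nrow(fx$tx$exons), 2] + 5L)
    for (p in sample(span, 40)) {
      size <- sample(1:3, 1)
      if (runif(1) < 0.5) {
        ref <- substr(fx$chrom, p, p)
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), size, TRUE),
                                 collapse = ""))
      } else {
        ref <- substr(fx$chrom, p, p + size)
        alt <- substr(fx$chrom, p, p)
      }
      v <- list(chrom = "chrT", pos = p, ref = ref, alt = alt)
      got_cons <- c(got_cons, annotate_indel(v, fx$tx, fx$genome)$consequence)
      want_cons <- c(want_cons,
                     oracle_annotate_indel(fx$chrom, p, ref, alt, fx$tx, ctx = ctx))
      n_checked <- n_checked + 1L
    }
  }
  expect_identical(got_cons, want_cons)
  expect_gte(n_checked, 300L)
})

test_that("strand symmetry: a minus-strand variant equals its mirrored plus construction", {
  fx <- random_gene_fixture(31, strand = "-")
  L <- nchar(fx$chrom)
  mirror_iv <- function(m) t(apply(m, 1, function(iv) c(L - iv[2] + 1L, L - iv[1] + 1L)))
  chrom_rc <- txpoly:::.revcomp(fx$chrom)
  genome_p <- make_genome(chrT = chrom_rc)
  tx_p <- make_tx("m", "chrT", "+", exons = t(mirror_iv(fx$tx$exons)),
                  cds = t(mirror_iv(fx$tx$cds)))
  set.seed(8)
  span <- fx$tx$exons[1, 1]:fx$tx$exons[nrow(fx$tx$exons), 2]
  comp <- function(b) chartr("ACGT", "TGCA", b)
  pairs <- lapply(sample(span, 60), function(p) {
    ref <- substr(fx$chrom, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    e_minus <- annotate_snp(snp_at("chrT", p, ref, alt), fx$tx, fx$genome)
    e_plus <- annotate_snp(snp_at("chrT", L - p + 1L, comp(ref), comp(alt)),
                           tx_p, genome_p)
    list(m = e_minus, p = e_plus)
  })
  expect_identical(vapply(pairs, function(x) x$m$consequence, ""),
                   vapply(pairs, function(x) x$p$consequence, ""))
  expect_identical(vapply(pairs, function(x) x$m$codon_index, NA_integer_),
                   vapply(pairs, function(x) x$p$codon_index, NA_integer_))
  expect_identical(vapply(pairs, function(x) x$m$ref_codon, ""),
                   vapply(pairs, function(x) x$p$ref_codon, ""))
})

test_that("nonsyn + syn + start/stop classes partition the CDS SNPs of complete transcripts", {
  fx <- random_gene_fixture(77, n_codons = 90)
  cds_pos <- txpoly:::.cds_genomic_positions(fx$tx)
  set.seed(3)
  cons <- vapply(sample(cds_pos, 150, replace = FALSE), function(p) {
    ref <- substr(fx$chrom, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    annotate_snp(snp_at("chrT", p, ref, alt), fx$tx, fx$genome)$consequence
  }, "")
  expect_true(all(cons %in% c("synonymous", "nonsynonymous", "start_loss",
                              "stop_gain", "stop_loss")))
})

test_that("effect summaries count carriers per line and planted classes match the manifest", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(simulation_config(seed = 23, chrom_length = 400000L, snp_rate = 0.001), dir)
  res <- filter_variants(normalize_indels(sim$calls_a), normalize_indels(sim$calls_b))
  eff <- annotate_variants(res$variants, sim$models, sim$genome)
  truth <- sim$manifest$variants
  planted <- truth[truth$origin %in% c("planted_class", "fab2c_like"), ]
  key_eff <- paste(eff$chrom, eff$pos, eff$ref, eff$alt)
  agree <- 0L
  for (i in seq_len(nrow(planted))) {
    k <- paste(planted$chrom[i], planted$pos[i], planted$ref[i], planted$alt[i])
    row <- eff[key_eff == k & !is.na(eff$gene_id) &
               eff$gene_id == planted$gene_id[i], ]
    expect_equal(nrow(row), 1)
    want <- if (planted$class[i] %in% c("utr_variant", "intron_variant"))
      planted$class[i] else planted$class[i]
    if (identical(row$consequence, want)) agree <- agree + 1L
  }
  expect_equal(agree, nrow(planted))  # every planted exemplar recovered

  # one SNP hom_alt in 2 lines: per-line count 1 for those two, total 1
  s <- effect_summary(eff, res$variants, type = "snp")
  lines <- variant_lines(res$variants)
  one <- eff[!is.na(eff$consequence) & eff$consequence == "stop_gain", ][1, ]
  carr <- strsplit(truth$carriers[truth$chrom == one$chrom & truth$pos == one$pos], ",")[[1]]
  sg_row <- s[s$class == "stop_gain", ]
  expect_true(all(sg_row[, intersect(carr, lines)] >= 1))
  # consistency: nonsyn + syn + start/stop classes == CDS SNP total
  expect_equal(sg_row$total + s$total[s$class == "nonsynonymous"] +
                 s$total[s$class == "synonymous"] +
                 s$total[s$class == "start_loss"] +
                 s$total[s$class == "stop_loss"],
               s$total[s$class == "cds"])
})

test_that("empty effect lists give an all-zero summary", {
  e <- make_calls("chr1", integer(0), character(0), character(0))
  eff <- annotate_variants(e, structure(list(genes = list(), by_chrom = list()),
                                        class = "gene_model_set"),
                           make_genome(chr1 = "ACGT"))
  s <- effect_summary(eff, e, type = "snp")
  expect_true(all(s$total == 0))
})

test_that("N/S ratio reproduces the published table arithmetic", {
  expect_equal(round(ns_ratio(n_nonsyn = 14372, n_syn = 16196), 2), 0.89)
  expect_equal(round(ns_ratio(n_nonsyn = 280, n_syn = 428), 2), 0.65)
  expect_equal(ns_ratio(n_nonsyn = 7, n_syn = 7), 1.0)
  expect_warning(r <- ns_ratio(n_nonsyn = 5, n_syn = 0), "undefined")
  expect_true(is.na(r))
})
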