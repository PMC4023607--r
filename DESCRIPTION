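Package: txpoly
Title: Transcript Sequence and Expression Polymorphism Analysis for
    Multi-Line RNA-seq Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize transcript polymorphisms segregating in a
    panel of inbred lines profiled by RNA-seq against a common reference
    genome. Covers consensus variant retention (two-caller intersection with
    depth, quality and cluster-window filters), codon-level consequence
    annotation of SNPs and small indels against GFF3 gene models
    (synonymous/non-synonymous calls, start/stop disruption, splice sites,
    frameshifts), z-score based expression-polymorphism calling on log2 FPKM,
    presence/absence variation, detection of runs of adjacent co-regulated
    genes (the expression signature of tandem copy-number amplification),
    shared-SNP spectra, SNP pseudo-molecule assembly with Tamura-Nei (1993)
    distances and neighbor-joining phylogeny with bootstrap support, sliding
    window landscape tracks, and functional-category enrichment. A seeded
    synthetic-data generator produces a full input set (FASTA, GFF3, two
    caller VCFs, FPKM table) with a ground-truth manifest so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
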