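---
title: "Methods: transcript polymorphism analysis in txpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript polymorphism analysis in txpoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`txpoly` analyses a panel of inbred lines profiled by RNA-seq against a
common reference: it retains consensus variant calls, predicts their
codon-level consequences, calls expression polymorphisms, detects
copy-number-like co-expression runs, and estimates the panel phylogeny
from SNP pseudo-molecules. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations. Upstream read processing — alignment, transcript assembly
and FPKM estimation — is out of scope: the package consumes the FPKM
matrix and the caller VCFs.

## Variant retention

Calls from two independent callers are combined under the most
conservative reading of "passing the filters and common to both methods":

1. **Intersection.** A call is retained iff an identical
   (chrom, pos, ref, alt) record appears in both callers. Indels are
   left-normalized first (shared suffix then prefix trimmed, one anchor
   base kept), since caller representations of the same indel differ and
   the raw intersection would be spuriously empty. Quality and depth come
   from caller A by default (`qual_from = "min"` takes the per-site
   minimum).
2. **Site filters.** `depth >= 5` and `qual >= 50`, both inclusive —
   boundary calls at depth 5 / qual 50 pass. Depth is tested first, so a
   doubly failing call is recorded as `fail_depth`. "Quality" is the VCF
   site QUAL; whether a genotype quality was meant instead is not
   decidable from the method description, so the threshold column is
   configurable.
3. **Cluster windows.** Any SNP belonging to a set of more than 2 SNPs
   within 10 consecutive bases is removed, together with every member of
   the offending cluster — the semantics of GATK VariantFiltration's
   cluster filter, which is the named tool; the alternative keep-first-two
   reading would retain an arbitrary subset. Indels neither populate nor
   are removed by the windows (the rule is stated for SNPs). Positions
   100/105/109 span 10 bases and are all removed; 100/105/110 span 11 and
   all pass.

The order intersection → site → cluster is fixed so that cluster windows
are evaluated on consensus calls only. The pipeline records counts removed
at each stage.

## Consequence annotation

Transcript models come from GFF3 (gene → mRNA → exon/CDS via ID/Parent).
External coordinates are 1-based inclusive throughout (GFF3/VCF
convention). Region labels partition every covered base exactly once:
`splice_site` (the 2 intronic bases at each intron end — the canonical
donor/acceptor core; the width is configurable) takes precedence over
`intron`; exonic bases resolve to `CDS`, `UTR5`/`UTR3` (strand-aware: the
5′ side of transcription) or `noncoding_exon`. Transcripts whose CDS
length is not a multiple of 3 are loaded but flagged incomplete and
excluded from codon-level calls — region labels are still assigned; no
reading frame is guessed.

For a CDS SNP the affected codon is located in transcript orientation
(minus-strand alleles complemented), mutated, and both codons translated
under the standard nuclear code (stop = `*`, codons containing N = `X`).
Classes are assigned disjointly under the precedence

> start_loss > stop_gain / stop_loss > nonsynonymous > synonymous,

with start_loss requiring the reference first codon to be ATG. Indels:
overlap with the annotated stop codon → `stoploss_indel`; otherwise CDS
overlap with size not divisible by 3 → `frameshift`, divisible →
`inframe_indel`; then splice-site, UTR, intron, intergenic. The reference
allele is checked against the genome at annotation time; a mismatch is a
data-integrity error, not a silent skip.

Genes with several transcripts are annotated against each; the gene-level
call is the most severe (the order above, frameshift ranked above
splice-site). For per-line counts a variant counts in a line iff that
line's genotype is heterozygous or homozygous-alternate; heterozygotes are
annotated identically to homozygotes.

The N/S ratio is reported over disjoint classes by default;
`include_stop_affecting = TRUE` folds start/stop-affecting SNPs into the
non-synonymous numerator, since premature-stop SNPs are amino-acid-changing
substitutions and published totals treat them that way. With zero
synonymous SNPs in scope the ratio is undefined and returned as `NA`.

## Expression polymorphisms

A gene is *expressed* iff its mean FPKM across lines is ≥ 0.5 (inclusive)
or it is detected (FPKM > 0) in every line. Organellar chromosomes can be
excluded by id. Z-scores are computed per expressed gene as

z = (log2(x + ε) − mean) / sd,

with pseudocount ε = 0.01 — far below the 0.5-FPKM expression threshold,
so it cannot distort flagged genes — and the sample SD (n − 1), the
conventional choice at n = 9; both are configurable. Zero-variance genes
get all-zero scores. A gene is polymorphic iff any line reaches |z| ≥ 2
(inclusive). Two per-line tallies are reported, because both conventions
appear in published summaries: every flagged gene-line cell, and each
polymorphic gene attributed only to its largest-|z| line.

Presence/absence variation bins genes by the number of lines with
FPKM > 0; fold-change outliers report gene-line pairs deviating ≥ 10-fold
from the gene mean among genes with mean ≥ 10 FPKM; cumulative-abundance
ranking returns the smallest top-gene prefix reaching a requested share of
total FPKM. For every stop-gain variant the carrier/non-carrier mean FPKM
ratio is computed; a mean near 1 indicates no systematic
nonsense-mediated-decay signal.

## Co-expression runs

Expressed genes are ordered by (chrom, start), ties broken by gene id;
non-expressed annotated genes do not interrupt adjacency, following the
expressed-gene ordering of the method. Per line, maximal runs of ≥ 3
consecutive genes with z ≥ 2 (up) or z ≤ −2 (down) are reported; runs
never span chromosomes and never mix directions — the copy-number
mechanism predicts coordinate same-direction change. Each member gene
carries its z-score and its fold-change versus the mean of the other
lines.

## Diversity and phylogeny

The shared-SNP spectrum counts SNPs carried by exactly k of n lines;
bin n is the case where the reference itself holds the minor allele.
Pseudo-molecules concatenate, per line, the reference or alternate
nucleotide at every SNP position, in genomic order, after dropping any
column that is heterozygous in a line, missing in a line, or identical
across all lines. Fewer than 4 surviving columns is an error (no tree is
estimable from that).

Pairwise distances use the closed-form Tamura–Nei (1993) estimator, with
the two transition classes (A↔G, C↔T) and transversions treated
separately and base frequencies estimated from the sequence pair
(averaged — the natural choice when no outgroup frequencies are
available). When equal frequencies and equal substitution rates hold, the
expression reduces exactly to Jukes–Cantor −(3/4)·ln(1 − 4p/3), which the
tests assert to 1e-9. A pair whose logarithm argument is non-positive is
*saturated*; in the distance matrix such entries are replaced by twice
the largest finite distance, with a warning, so neighbor joining stays
defined. Note that pseudo-molecule alignments are restricted to
polymorphic columns, so distances are intrinsically large and saturation
is a realistic concern, not a pathological corner.

Trees are built by Saitou–Nei neighbor joining: ties in the Q criterion
break to the lowest index pair, making the result deterministic, and a
negative branch length is clamped to zero with the deficit shifted to its
sister branch so path lengths are preserved. On additive matrices the
input distances are reproduced exactly (asserted to 1e-9), and the
implementation agrees with `ape::nj` on random matrices in the tests —
`ape` serves as the independent reference, never as the implementation.
Bootstrap support resamples alignment columns with replacement, rebuilds
the TN93 + NJ tree per replicate, and reports for each internal
bipartition the fraction of replicates containing it; the procedure is
seeded and reproducible. A full maximum-likelihood tree search is a
non-goal: distances + NJ + bootstrap is the same family of methods used to
seed such searches, and branch lengths and supports are comparable but not
identical to ML results.

## Landscape tracks, enrichment, report arithmetic

Sliding windows are 1 Mb wide with 0.1 Mb steps by default, truncated at
the chromosome end. Features are assigned to windows by their (start)
position, so with step = width the window counts conserve the feature
total; an overlap mode exists for plotting parity. Per-gene SNP density is
SNPs per kb of transcribed sequence, the transcribed length being the
union of the gene's exons over its transcripts.

Category enrichment is the one-sided Fisher exact test (hypergeometric
upper tail via `phyper`) per category against a user-supplied background
— the natural background is the expressed genes present in the category
table. Raw p-values are reported; no multiple-testing correction, matching
how such screens are usually reported at this scale.

`published_table_ratios()` recomputes derived figures from the bundled
published per-line count tables of the nine-line soybean seed panel (GEO
GSE56297). Two quirks of those printed tables are handled deliberately:
the "percent expressed" total row is the unweighted mean of the
per-category percentages (the weighted value would be 70.6, the printed
one 73.87), and the printed non-synonymous + synonymous counts
(14,372 + 16,196 = 30,568) slightly exceed the printed CDS SNP total
(30,535), so the published class rows cannot be a disjoint partition; the
package's own summaries are disjoint under the stated precedence.

## The synthetic study generator

`simulate_study()` emulates the structure of the motivating design: nine
diploid inbred lines related by a known random tree, 200 gene models on
two 1-Mb chromosomes, ~2.5 variants per kb, FPKM with planted signals.
Specifics, chosen once as study conditions:

* **Genes** have 1–4 exons, 30–80 nt 5′ UTRs, 50–150 nt 3′ UTRs, 60–300
  codons, proper ORFs (ATG start, no internal stop), either strand. One
  fixture gene carries GAC (Asp) at codon 77 with a planted G→A
  first-position SNP in exactly one line — the stearoyl-ACP-desaturase
  style worked example (D77N).
* **Variants** are placed on branches of the true tree with probability
  proportional to branch length (infinite sites), so the genotype matrix
  admits a perfect phylogeny equal to the generating tree; 5% of
  background variants are carried by all nine lines (reference holds the
  minor allele). Transitions are drawn at 2:1 over transversions. At least
  one exemplar of every consequence class is planted (two by default).
  Variants keep ≥ 11 bp spacing except deliberately planted
  3-SNPs-in-10-bp decoys, so the cluster filter's removals equal exactly
  the decoy set. Heterozygous (3% of carrier cells) and missing (1% of
  cells) genotypes are injected into background variants only.
* **Callers**: both callers see every planted exemplar; background
  variants are dropped per caller at a 3% false-negative rate and each
  caller gains 2% private false positives; planted depth decoys (< 5
  reads) and quality decoys (< 50) fail the site filters in both callers.
  Depth is 5 + Poisson(11), i.e. ~16 reads on average.
* **Expression**: per-gene baseline log2 FPKM ~ Normal(3, 2) across genes,
  per-line noise σ = 0.3; planted outliers shift exactly one line by
  Δ = 3 log2 units (σ and Δ are set so that |z| ≥ 2 detection is
  near-certain at n = 9); the planted amplified cluster multiplies four
  adjacent genes by 15.5/9.6/8.0/9.0 in one line; presence/absence genes
  are zeroed in a random subset of lines. Planted feature gene sets are
  mutually disjoint so each signal is measurable in isolation. An optional
  factor multiplies carrier-line FPKM of planted stop-gain genes (default
  1: no decay effect).

**What the generator does not emulate:** read-level noise (FPKM
estimation error, mapping bias, multi-mapping loss), linkage between
sequence and expression variation, recurrent mutation (available behind
no flag here; infinite sites is assumed), gene families/paralogy,
organellar contamination, and real soybean genome structure. Passing the
planted-truth tests therefore demonstrates correctness of the algorithms
under the stated noise models, not performance on real libraries.

## Problem sizes and numerical notes

The default study (two 1-Mb chromosomes, ~5,000 variants, ~3,400
surviving pseudo-molecule columns, 200 bootstrap replicates) was chosen so
that every internal edge of a random nine-taxon tree receives ample
column support: with transition-biased mutations the TN93 estimator's
saturation boundary sits near pairwise difference p = 0.6 while the most
divergent line pairs reach p ≈ 0.55, and resampling variance at a few
hundred columns would let replicates cross that boundary and destabilize
short internal edges. At ~3,400 columns all true bipartitions reach
support 1.0 across seeds. Analyses of full-scale data (tens of thousands
of columns) sit further from the boundary, not closer.

A known property of the z-score rule deserves emphasis: with Gaussian
per-line noise and n = 9, the per-cell probability that a *null* gene-line
reaches |z| ≥ 2 is about 2% (it maps to a t7 tail), and about 18% of null
genes have some line flagged. The |Z| ≥ 2 screen is therefore a
candidate-generating filter, not an error-controlled test — consistent
with roughly a quarter of genes being flagged in real panels of this
shape. The package reports the measured false-flag rate alongside recall
on synthetic data rather than pretending the rule is more specific than
it is.

## Limitations

* Biallelic variants only; multi-allelic records are split, structural
  variants are out of scope.
* Compound heterozygous/haplotype-aware codon reconstruction is not
  attempted; each variant is annotated in isolation.
* The phylogeny module estimates distances and an NJ topology; it does
  not perform ML optimization, model selection, rooting or rate
  heterogeneity.
* Enrichment p-values are raw and the 2×2 background is the caller's
  choice; with small categories the test is conservative.
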