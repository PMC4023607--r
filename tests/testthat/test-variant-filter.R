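# Two-caller intersection, site filters, cluster-window rule and their
# composition.

test_that("intersection keeps only identical (chrom,pos,ref,alt) records", {
  a <- make_calls("chr1", c(100, 200, 300), ref = c("C", "C", "G"),
                  alt = c("T", "T", "A"))
  b <- make_calls("chr1", c(100, 300), ref = c("C", "G"), alt = c("G", "A"))
  got <- intersect_callsets(a, b)
  # pos 100 has a different alt in B (C->T vs C->G): dropped; 200 A-only
  expect_equal(got$pos, 300)
  expect_error(intersect_callsets(a[c(2, 1, 3), ], b), "sorted")
})

test_that("qual/depth come from caller A by default, per-site minimum on request", {
  a <- make_calls("chr1", 100, "C", "T", qual = 80, depth = 10)
  b <- make_calls("chr1", 100, "C", "T", qual = 60, depth = 30)
  expect_equal(intersect_callsets(a, b)$qual, 80)
  got <- intersect_callsets(a, b, qual_from = "min")
  expect_equal(got$qual, 60)
  expect_equal(got$depth, 10)
})

test_that("indel left-normalization reconciles caller representations", {
  # same 1bp deletion written two ways: pos 10 ref ACT alt AC == pos 11 ref CT alt C
  a <- make_calls("chr1", 10, "ACT", "AC")
  b <- make_calls("chr1", 11, "CT", "C")
  na <- normalize_indels(a); nb <- normalize_indels(b)
  expect_equal(na[, c("pos", "ref", "alt")], nb[, c("pos", "ref", "alt")])
  expect_equal(nrow(intersect_callsets(na, nb)), 1)
  # SNP dressed as MNP normalizes to a plain SNP
  m <- normalize_indels(make_calls("chr1", 20, "TTA", "TTG"))
  expect_equal(m$pos, 22); expect_equal(m$ref, "A"); expect_equal(m$alt, "G")
})

test_that("site filters are inclusive at depth 5 / qual 50 and record fail reasons", {
  calls <- make_calls("chr1", c(10, 20, 30, 40), "C", "T",
                      qual = c(50, 99, 49, 49), depth = c(5, 4, 20, 4))
  got <- apply_site_filters(calls)
  expect_equal(got$filter_status,
               c("pass", "fail_depth", "fail_qual", "fail_depth"))
  # 200 random calls against the brute-force predicate
  set.seed(1)
  rnd <- make_calls("chr1", seq(100, by = 50, length.out = 200), "C", "T",
                    qual = sample(30:70, 200, TRUE), depth = sample(1:10, 200, TRUE))
  got <- apply_site_filters(rnd)
  expect_equal(got$filter_status == "pass", oracle_site_pass(rnd))
})

test_that("cluster filter removes all members of >2-SNPs-in-10bp windows", {
  trio <- apply_cluster_filter(make_calls("chr1", c(100, 105, 109), "C", "T"))
  expect_equal(trio$filter_status, rep("fail_cluster", 3))  # span 10
  ok <- apply_cluster_filter(make_calls("chr1", c(100, 105, 110), "C", "T"))
  expect_equal(ok$filter_status, rep("pass", 3))            # span 11
  pair <- apply_cluster_filter(make_calls("chr1", c(100, 101), "C", "T"))
  expect_equal(pair$filter_status, rep("pass", 2))          # pairs allowed
  # indels neither fail nor break SNP windows
  mixed <- make_calls("chr1", c(100, 104, 105, 109), ref = c("C", "CA", "C", "C"),
                      alt = c("T", "C", "T", "T"))
  got <- apply_cluster_filter(mixed)
  expect_equal(got$filter_status[got$pos == 104], "pass")
  expect_equal(got$filter_status[got$pos != 104], rep("fail_cluster", 3))
})

test_that("cluster filter equals exhaustive window enumeration on random inputs", {
  set.seed(99)
  for (rep in 1:5) {
    pos <- sort(sample(1:400, 60))
    pos <- pos[!duplicated(pos)]
    calls <- make_calls("chr1", pos, "C", "T")
    got <- apply_cluster_filter(calls)
    expect_equal(got$filter_status == "fail_cluster",
                 oracle_cluster_fail(calls$chrom, calls$pos))
  }
})

test_that("the constructed six-case call set leaves exactly the designed survivor", {
  lines <- c("l1", "l2")
  mk <- function(pos, ref, alt, qual, depth) {
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt, qual = qual,
               depth = depth, l1 = "hom_alt", l2 = "hom_ref",
               stringsAsFactors = FALSE)
  }
  a <- variant_calls(rbind(
    mk(100, "A", "T", 90, 20), mk(105, "C", "G", 90, 20), mk(109, "G", "A", 90, 20),
    mk(1000, "A", "G", 50, 5),    # designed survivor (boundary pass)
    mk(2000, "C", "T", 99, 4),    # fail_depth
    mk(3000, "G", "A", 49, 20),   # fail_qual
    mk(4000, "T", "C", 90, 20),   # caller A only
    mk(5000, "C", "T", 90, 20)    # allele mismatch with B
  ), lines)
  b <- variant_calls(rbind(
    mk(100, "A", "T", 90, 20), mk(105, "C", "G", 90, 20), mk(109, "G", "A", 90, 20),
    mk(1000, "A", "G", 77, 9),
    mk(2000, "C", "T", 99, 4),
    mk(3000, "G", "A", 49, 20),
    mk(5000, "C", "G", 90, 20)
  ), lines)
  res <- filter_variants(a, b)
  expect_equal(res$variants$pos, 1000)
  st <- setNames(res$all$filter_status, res$all$pos)
  expect_equal(unname(st[c("100", "105", "109")]), rep("fail_cluster", 3))
  expect_equal(unname(st["2000"]), "fail_depth")
  expect_equal(unname(st["3000"]), "fail_qual")
  expect_equal(unname(st["4000"]), "fail_single_caller")
  expect_false("5000" %in% names(st[st == "pass"]))
  expect_equal(res$audit$n[res$audit$stage == "pass"], 1)
})

test_that("filtering is order-insensitive, monotone in thresholds, and idempotent", {
  set.seed(7)
  n <- 120
  pos <- sort(sample(1:5000, n))
  base <- make_calls("chr1", pos, "C", "T",
                     qual = sample(30:90, n, TRUE), depth = sample(1:12, n, TRUE))
  b <- base[sample(n, 100), ]
  b <- b[order(b$chrom, b$pos), ]
  attr(b, "lines") <- attr(base, "lines")
  res <- filter_variants(base, b)
  # permuting then re-sorting caller A does not change the pass set
  perm <- base[sample(n), ]
  perm <- perm[order(perm$chrom, perm$pos), ]
  attr(perm, "lines") <- attr(base, "lines")
  expect_equal(filter_variants(perm, b)$variants$pos, res$variants$pos)
  # raising thresholds never enlarges the pass set
  stricter <- filter_variants(base, b, min_depth = 8, min_qual = 70)
  expect_true(all(stricter$variants$pos %in% res$variants$pos))
  # filtering an already-passing set removes nothing
  again <- filter_variants(res$variants, res$variants)
  expect_equal(nrow(again$variants), nrow(res$variants))
})

test_that("empty inputs produce empty outputs with zero counts", {
  e <- make_calls("chr1", integer(0), character(0), character(0))
  res <- filter_variants(e, e)
  expect_equal(nrow(res$variants), 0)
  expect_equal(res$audit$n[res$audit$stage == "pass"], 0)
})

test_that("VCF round trip preserves calls, genotypes and depth", {
  dir <- withr::local_tempdir()
  calls <- make_calls("chr1", c(10, 20, 35), ref = c("A", "C", "CTT"),
                      alt = c("G", "T", "C"), qual = c(60, 70, 80),
                      depth = c(10, 11, 12))
  calls$l1 <- c("hom_alt", "het", "missing")
  calls$l2 <- c("hom_ref", "hom_alt", "hom_alt")
  p <- file.path(dir, "x.vcf")
  write_variant_vcf(calls, p)
  back <- read_caller_vcf(p)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$depth, calls$depth)
  expect_equal(back$l1, calls$l1)
  expect_equal(back$l2, calls$l2)
})
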