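# Expressed-gene rule, z-scores, polymorphism calling, PAV, fold-change
# outliers, cumulative abundance and the premature-stop expression ratio.

mat <- function(v, lines = paste0("L", seq_len(ncol(v)))) {
  dimnames(v) <- list(paste0("g", seq_len(nrow(v))), lines)
  v
}

test_that("expressed-gene rule: mean >= 0.5 inclusive OR present in all lines", {
  m <- mat(rbind(rep(0.5, 9),            # mean exactly 0.5 -> expressed
                 rep(0.1, 9),            # mean 0.1 but present in all -> expressed
                 c(4.4, rep(0, 8)),      # mean 0.49, a zero line -> not expressed
                 rep(0, 9)))             # all zeros -> not expressed
  expect_equal(unname(classify_expressed(m)), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("z-scores use sample SD on log2 FPKM and standardize exactly", {
  m <- mat(matrix(2^(0:8), 1, 9))
  z <- expression_zscores(m, pseudocount = 0)
  expect_equal(z$z[1, 1], -1.4606, tolerance = 1e-4)
  # direct formula as oracle, including the pseudocount
  set.seed(5)
  r <- mat(matrix(rexp(90, 0.1), 10, 9))
  zt <- expression_zscores(r)
  lg <- log2(r + 0.01)
  want <- (lg - rowMeans(lg)) / apply(lg, 1, sd)
  expect_equal(zt$z, want, tolerance = 1e-12)
  # normalization invariant: sum 0, sample SD 1
  expect_true(all(abs(rowSums(zt$z)) < 1e-9))
  expect_true(all(abs(apply(zt$z, 1, sd) - 1) < 1e-9))
  # zero variance -> all-zero scores; single line -> error
  cz <- expression_zscores(mat(matrix(7, 1, 9)))
  expect_true(all(cz$z == 0))
  expect_error(expression_zscores(mat(matrix(1, 3, 1))), "at least 2 lines")
})

test_that("scale equivariance: scaling FPKM by c (with scaled pseudocount) keeps z", {
  set.seed(6)
  m <- mat(matrix(rexp(45, 0.05), 5, 9))
  z1 <- expression_zscores(m, pseudocount = 0.01)
  z2 <- expression_zscores(m * 50, pseudocount = 0.01 * 50)
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
})

test_that("polymorphism flags are inclusive at |z| = 2 and tally directions", {
  z <- list(z = mat(rbind(c(2.0, rep(-0.25, 8)),
                          c(rep(0.1, 8), -1.9))))
  class(z) <- "zscore_table"
  pol <- expression_polymorphisms(z)
  expect_equal(pol$per_gene$polymorphic, c(TRUE, FALSE))
  expect_equal(pol$per_gene$direction[1], "up")
  expect_equal(pol$per_line$up[1], 1)
  expect_equal(pol$n_polymorphic, 1)
})

test_that("planted outliers are recovered by the z-score rule", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(simulation_config(seed = 31, chrom_length = 400000L, snp_rate = 0.001), dir)
  expr <- read_fpkm(sim$paths$fpkm)
  expressed <- classify_expressed(expr$fpkm)
  zt <- expression_zscores(expr$fpkm[expressed, , drop = FALSE])
  pol <- expression_polymorphisms(zt)
  truth <- sim$manifest$outliers
  truth <- truth[truth$gene_id %in% rownames(zt$z), ]
  hit <- mapply(function(g, l, d) {
    pol$flags[g, l] == (if (d == "up") 1 else -1)
  }, truth$gene_id, truth$line, truth$direction)
  expect_gte(mean(hit), 0.95)
})

test_that("PAV bins partition the present genes and match the planted manifest", {
  m <- mat(rbind(c(5, rep(0, 8)), rep(2, 9), c(1, 1, rep(0, 7))))
  pav <- pav_table(m)
  expect_equal(pav$n_genes[c(1, 2, 9)], c(1, 1, 1))
  expect_equal(sum(pav$n_genes), 3)
  expect_equal(pav$mean_fpkm[1], 5)
  dir <- withr::local_tempdir()
  sim <- simulate_study(simulation_config(seed = 37, n_genes = 120, chrom_length = 400000L, snp_rate = 0.001,
                                          n_outliers = 15, n_pav = 12), dir)
  expr <- read_fpkm(sim$paths$fpkm)
  present <- expr$fpkm > 0
  for (i in seq_len(nrow(sim$manifest$pav))) {
    g <- sim$manifest$pav$gene_id[i]
    want <- sort(strsplit(sim$manifest$pav$present_lines[i], ",")[[1]])
    expect_equal(sort(colnames(present)[present[g, ]]), want)
  }
  pav <- pav_table(expr$fpkm)
  expect_equal(sum(pav$n_genes), sum(rowSums(present) > 0))
})

test_that("fold-change outliers match hand enumeration", {
  m <- mat(rbind(c(rep(100, 8), 100 / 318 * 9 / (8 + 1 / 318) * 8),  # ~318x down
                 rep(50, 9),
                 c(rep(1, 8), 30)), lines = paste0("L", 1:9))
  # construct exactly: line value v s.t. mean/v = 318
  v <- numeric(9); v[1:8] <- 100
  v[9] <- sum(v[1:8]) / (318 * 9 - 1)
  m[1, ] <- v
  out <- fold_change_outliers(m, min_mean = 10, min_fold = 10)
  expect_equal(nrow(out), 1)  # gene 3 fails min_mean; gene 2 constant
  expect_equal(out$gene_id, "g1")
  expect_equal(out$direction, "down")
  expect_equal(out$fold, 318, tolerance = 1e-9)
  expect_equal(nrow(fold_change_outliers(mat(matrix(20, 4, 9)))), 0)
  # zero in a high-mean gene gives an infinite fold, reported once
  z <- mat(rbind(c(rep(90, 8), 0)))
  expect_true(is.infinite(fold_change_outliers(z)$fold))
})

test_that("cumulative abundance prefixes equal the brute-force cumulative sum", {
  eq <- mat(matrix(1, 10, 9))
  expect_equal(unname(cumulative_abundance(eq, shares = 0.5)$prefix), 5)
  one <- mat(rbind(rep(90, 9), matrix(10 / 9, 9, 9)))
  expect_equal(unname(cumulative_abundance(one, shares = 0.5)$prefix), 1)
  set.seed(8)
  r <- mat(matrix(2^rnorm(180, 3, 2), 20, 9))
  ca <- cumulative_abundance(r, shares = c(0.11, 0.5))
  shr <- rowMeans(sweep(r, 2, colSums(r), "/"))
  shr <- sort(shr / sum(shr), decreasing = TRUE)
  expect_equal(unname(ca$prefix[1]), unname(which(cumsum(shr) >= 0.11)[1]))
  expect_equal(unname(ca$prefix[2]), unname(which(cumsum(shr) >= 0.5)[1]))
})

test_that("premature-stop expression ratio recovers planted suppression", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(simulation_config(seed = 41, n_per_class = 4, chrom_length = 400000L, snp_rate = 0.001,
                                          stop_gain_expression_factor = 0.3),
                        dir)
  res <- filter_variants(normalize_indels(sim$calls_a),
                         normalize_indels(sim$calls_b))
  eff <- annotate_variants(res$variants, sim$models, sim$genome)
  expr <- read_fpkm(sim$paths$fpkm)
  sg <- stop_gain_expression_ratio(expr$fpkm, eff, res$variants)
  # suppression is planted only at the manifest's stop-gain exemplars;
  # background variants that happen to create stops stay unsuppressed
  truth <- sim$manifest$variants
  planted_sg <- truth$gene_id[!is.na(truth$class) & truth$class == "stop_gain"]
  planted <- sg$per_variant[sg$per_variant$gene_id %in% planted_sg, ]
  expect_gte(nrow(planted), 3)
  expect_equal(mean(planted$ratio), 0.3, tolerance = 0.15)
  # identical carriers and non-carriers -> ratio exactly 1
  calls <- make_calls("chr1", 5, "C", "T", lines = c("a", "b", "c", "d"))
  calls$a <- "hom_alt"; calls$b <- "hom_alt"; calls$c <- "hom_ref"; calls$d <- "hom_ref"
  eff1 <- data.frame(chrom = "chr1", pos = 5L, ref = "C", alt = "T",
                     gene_id = "g1", transcript_id = "g1.1", region = "CDS",
                     consequence = "stop_gain", codon_index = 3L,
                     ref_codon = "TAC", alt_codon = "TAA", ref_aa = "Y",
                     alt_aa = "*", stringsAsFactors = FALSE)
  f <- matrix(6, 1, 4, dimnames = list("g1", c("a", "b", "c", "d")))
  expect_equal(stop_gain_expression_ratio(f, eff1, calls)$mean_ratio, 1)
})
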