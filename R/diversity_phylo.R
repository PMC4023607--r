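# Genetic diversity and phylogeny from the retained SNPs: shared-SNP
# spectrum, pseudo-molecule assembly with the position filters (no
# heterozygous, missing or monomorphic columns), closed-form Tamura-Nei
# (1993) pairwise distances, Saitou-Nei neighbor joining and bootstrap
# support over resampled alignment columns.

#' Build a SNP genotype matrix from a call set
#'
#' @param calls A call set restricted to SNPs (non-SNPs are dropped).
#' @return List: `geno` (sites x lines character matrix with entries
#'   ref/alt/het/missing) and `info` (site table chrom/pos/ref/alt, sorted,
#'   unique).
#' @export
snp_genotype_matrix <- function(calls) {
  lines <- variant_lines(calls)
  calls <- calls[is_snp(calls), , drop = FALSE]
  calls <- calls[!duplicated(.variant_key(calls)), , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  code <- c(hom_ref = "ref", het = "het", hom_alt = "alt", missing = "missing")
  geno <- vapply(lines, function(l) unname(code[calls[[l]]]),
                 character(nrow(calls)))
  if (nrow(calls) == 1) geno <- matrix(geno, nrow = 1, dimnames = list(NULL, lines))
  list(geno = geno,
       info = data.frame(chrom = calls$chrom, pos = calls$pos,
                         ref = calls$ref, alt = calls$alt,
                         stringsAsFactors = FALSE))
}

#' Shared-SNP spectrum
#'
#' Counts SNPs carried (het or hom_alt, i.e. genotype `het` or `alt`) by
#' exactly k of the n lines, for k = 1..n. Bin 1 holds line-specific SNPs;
#' bin n holds SNPs where the reference carries the unique allele. SNPs
#' with no carrier are not binned.
#'
#' @param geno Sites x lines genotype matrix from [snp_genotype_matrix()].
#' @return Named integer vector of length n (names "1".."n").
#' @export
shared_snp_spectrum <- function(geno) {
  n <- ncol(geno)
  k <- rowSums(geno == "alt" | geno == "het")
  vapply(1:n, function(b) sum(k == b), 0L) |> setNames(as.character(1:n))
}

#' Assemble pseudo-molecule sequences for phylogeny
#'
#' Drops every SNP column that is heterozygous in any line, missing in any
#' line, or identical across all lines (monomorphic), then emits per line
#' the reference or alternate nucleotide at each surviving position,
#' concatenated in genomic order.
#'
#' @param geno Sites x lines genotype matrix.
#' @param info Matching site table (chrom/pos/ref/alt).
#' @param min_columns Minimum surviving columns (default 4); fewer is an
#'   error (tree not estimable).
#' @return List: `seqs` (named character vector, one equal-length sequence
#'   per line) and `provenance` (site table of the surviving columns with
#'   the drop accounting in attributes `n_dropped_het`, `n_dropped_missing`,
#'   `n_dropped_monomorphic`).
#' @export
build_pseudomolecules <- function(geno, info, min_columns = 4L) {
  has_het <- apply(geno == "het", 1, any)
  has_missing <- apply(geno == "missing", 1, any)
  mono <- apply(geno, 1, function(r) length(unique(r)) == 1L)
  keep <- !(has_het | has_missing | mono)
  if (sum(keep) < min_columns)
    .stopf("only %d SNP column(s) survive the phylogeny filters (need >= %d)",
           sum(keep), min_columns)
  g <- geno[keep, , drop = FALSE]
  inf <- info[keep, , drop = FALSE]
  seqs <- vapply(colnames(g), function(l) {
    paste(ifelse(g[, l] == "alt", inf$alt, inf$ref), collapse = "")
  }, "")
  prov <- inf
  rownames(prov) <- NULL
  attr(prov, "n_dropped_het") <- sum(has_het)
  attr(prov, "n_dropped_missing") <- sum(has_missing & !has_het)
  attr(prov, "n_dropped_monomorphic") <- sum(mono & !has_het & !has_missing)
  list(seqs = seqs, provenance = prov)
}

#' Tamura-Nei (1993) pairwise distance
#'
#' Closed-form TN93 distance from the two transition proportions (purines
#' and pyrimidines separately), the transversion proportion, and the
#' empirical base frequencies of the sequence pair (averaged over both
#' sequences). Saturated pairs (any logarithm argument <= 0) return `NA`.
#'
#' @param seq_i,seq_j Equal-length A/C/G/T strings, no gaps.
#' @return Distance in substitutions per site, or `NA` if saturated.
#' @export
tn93_distance <- function(seq_i, seq_j) {
  if (nchar(seq_i) != nchar(seq_j)) .stopf("sequences differ in length")
  x <- strsplit(seq_i, "")[[1]]
  y <- strsplit(seq_j, "")[[1]]
  if (any(!(c(x, y) %in% c("A", "C", "G", "T"))))
    .stopf("sequences must be over A/C/G/T")
  n <- length(x)
  freq <- (table(factor(x, levels = c("A", "C", "G", "T"))) +
           table(factor(y, levels = c("A", "C", "G", "T")))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- x != y
  pair <- paste(pmin(x, y), pmax(x, y))  # unordered
  P1 <- sum(diff & pair == "A G") / n    # purine transitions
  P2 <- sum(diff & pair == "C T") / n    # pyrimidine transitions
  Q <- sum(diff) / n - P1 - P2           # transversions
  if (gA * gG == 0 || gC * gT == 0 || gR * gY == 0) {
    # degenerate composition: no information for one of the terms
    if ((gA * gG == 0 && P1 > 0) || (gC * gT == 0 && P2 > 0)) return(NA_real_)
  }
  k1 <- if (gA * gG > 0) 2 * gA * gG / gR else 0
  k2 <- if (gC * gT > 0) 2 * gC * gT / gY else 0
  k3 <- 2 * (gR * gY -
             (if (gR > 0) gA * gG * gY / gR else 0) -
             (if (gY > 0) gC * gT * gR / gY else 0))
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)  # saturated
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  max(d, 0)
}

#' TN93 distance matrix
#'
#' All pairwise [tn93_distance()] values. Saturated pairs are replaced by
#' twice the maximum finite distance in the matrix, with a warning, so that
#' neighbor joining stays defined on extreme inputs.
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
tn93_matrix <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- tn93_distance(seqs[[i]], seqs[[j]])
    }
  }
  if (anyNA(D)) {
    repl <- 2 * max(D, na.rm = TRUE)
    .warnf("%d saturated pair(s) replaced by twice the maximum finite distance",
           sum(is.na(D)) / 2)
    D[is.na(D)] <- repl
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix. Negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' branch; ties in the Q criterion are broken by the lowest index pair, so
#' the result is deterministic. The returned tree is unrooted with a
#' trifurcation at the final join.
#'
#' @param D Symmetric numeric matrix, zero diagonal, >= 4 taxa (3 accepted:
#'   the star join with three-point branch lengths).
#' @return An [ape] `phylo` object with branch lengths in the units of `D`.
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3) .stopf("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-9 || any(abs(diag(D)) > 1e-12))
    .stopf("distance matrix must be symmetric with zero diagonal")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels  # newick fragment per active node
  active <- seq_len(n)
  Dm <- D

  join2 <- function(i, j, bi, bj) {
    bi <- max(bi, 0); bj <- max(bj, 0)
    sprintf("(%s:%.10g,%s:%.10g)", nodes[i], bi, nodes[j], bj)
  }

  while (length(active) > 3) {
    m <- length(active)
    sub <- Dm[active, active, drop = FALSE]
    r <- rowSums(sub)
    Q <- (m - 2) * sub - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest index pair among ties
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    d_ij <- sub[i, j]
    bi <- d_ij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d_ij - bi
    # clamp negatives, moving the deficit to the sister branch
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    ai <- active[i]; aj <- active[j]
    new_label <- join2(ai, aj, bi, bj)
    d_new <- (sub[i, ] + sub[j, ] - d_ij) / 2
    # grow the matrix with the new node
    Dm <- rbind(cbind(Dm, 0), 0)
    new_idx <- nrow(Dm)
    Dm[new_idx, active] <- d_new
    Dm[active, new_idx] <- d_new
    Dm[new_idx, new_idx] <- 0
    nodes <- c(nodes, new_label)
    active <- c(setdiff(active, c(ai, aj)), new_idx)
  }
  a <- active
  if (length(a) == 3) {
    d12 <- Dm[a[1], a[2]]; d13 <- Dm[a[1], a[3]]; d23 <- Dm[a[2], a[3]]
    b1 <- max((d12 + d13 - d23) / 2, 0)
    b2 <- max((d12 + d23 - d13) / 2, 0)
    b3 <- max((d13 + d23 - d12) / 2, 0)
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   nodes[a[1]], b1, nodes[a[2]], b2, nodes[a[3]], b3)
  } else {  # exactly 2 left (n == 3 input collapses here only when n < 3)
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", nodes[a[1]], Dm[a[1], a[2]] / 2,
                   nodes[a[2]], Dm[a[1], a[2]] / 2)
  }
  ape::read.tree(text = nwk)
}

#' Bootstrap support for the NJ tree of a pseudo-molecule alignment
#'
#' Resamples alignment columns with replacement, rebuilds the TN93 + NJ tree
#' per replicate, and reports for every internal bipartition of the main
#' tree the fraction of replicate trees containing it. Seeded and
#' reproducible.
#'
#' @param seqs Named character vector of equal-length sequences (as from
#'   [build_pseudomolecules()]).
#' @param replicates Number of bootstrap replicates (default 1000). With 0
#'   replicates the tree is returned without supports.
#' @param seed Integer seed for the resampling.
#' @return List: `tree` (the main `phylo`, with `node.label` = support as a
#'   fraction in [0, 1] for internal nodes) and `support` (numeric vector).
#' @export
bootstrap_support <- function(seqs, replicates = 1000, seed = 1) {
  main <- nj_tree(tn93_matrix(seqs))
  if (replicates == 0) return(list(tree = main, support = NULL))
  cols <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(cols) <- names(seqs)
  L <- ncol(cols)
  set.seed(seed)
  reps <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    pick <- sample.int(L, L, replace = TRUE)
    rs <- apply(cols[, pick, drop = FALSE], 1, paste, collapse = "")
    reps[[b]] <- nj_tree(tn93_matrix(rs))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  support <- counts / replicates
  main$node.label <- support
  list(tree = main, support = support)
}
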