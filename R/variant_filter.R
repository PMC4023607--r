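# Variant retention rules: two-caller intersection, depth/quality site
# filters, and the cluster-window rule, composed in that fixed order so the
# cluster windows are evaluated on consensus calls only.
#
# A call set is a data.frame with columns chrom, pos (1-based), ref, alt,
# qual, depth, followed by one genotype column per line with values in
# {hom_ref, het, hom_alt, missing}; the line ids are carried in the "lines"
# attribute.

.GENO_CODES <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a variant call set
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `depth` and one genotype column per line.
#' @param lines Character vector of line ids (must match genotype columns).
#' @return The validated call set with a `lines` attribute.
#' @export
variant_calls <- function(df, lines) {
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("call set lacks column(s): %s", paste(miss, collapse = ", "))
  if (!all(lines %in% names(df)))
    .stopf("genotype column(s) missing for line(s): %s",
           paste(setdiff(lines, names(df)), collapse = ", "))
  if (any(df$ref == df$alt)) .stopf("ref and alt alleles must differ")
  if (any(!is.finite(df$qual)) || any(!is.finite(df$depth)))
    .stopf("qual and depth must be finite")
  if (any(df$qual < 0) || any(df$depth < 0))
    .stopf("qual and depth must be non-negative")
  bad <- grepl("[^ACGT]", df$ref) | grepl("[^ACGT]", df$alt)
  if (any(bad)) .stopf("alleles must be non-empty A/C/G/T strings")
  for (l in lines) {
    if (!all(df[[l]] %in% .GENO_CODES))
      .stopf("genotype column %s has values outside {%s}", l,
             paste(.GENO_CODES, collapse = ", "))
  }
  df <- df[, c(need, setdiff(names(df), need)), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "lines") <- lines
  df
}

#' Line ids of a call set
#' @param calls A call set.
#' @return Character vector of line ids.
#' @export
variant_lines <- function(calls) attr(calls, "lines")

#' Is each call a SNP?
#' @param calls A call set.
#' @return Logical vector: both alleles of length 1.
#' @export
is_snp <- function(calls) nchar(calls$ref) == 1L & nchar(calls$alt) == 1L

.variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

.check_sorted <- function(calls, what) {
  o <- order(calls$chrom, calls$pos)
  if (!identical(o, seq_len(nrow(calls))))
    .stopf("%s must be sorted by (chrom, pos); sort the input first", what)
}

#' Left-normalize indel representations
#'
#' Trims shared trailing then leading bases from ref/alt pairs, moving the
#' position to the leftmost changed base (leading trim keeps one anchor base
#' for indels, VCF style). Caller representations of the same indel differ;
#' without normalization the two-caller intersection is spuriously empty.
#'
#' @param calls A call set.
#' @return The call set with normalized `pos`, `ref`, `alt`, re-sorted.
#' @export
normalize_indels <- function(calls) {
  for (i in which(nchar(calls$ref) > 1L | nchar(calls$alt) > 1L)) {
    r <- calls$ref[i]; a <- calls$alt[i]; p <- calls$pos[i]
    # trim common suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix; both alleles keep at least one base (VCF anchor)
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p <- p + 1L
    }
    calls$ref[i] <- r; calls$alt[i] <- a; calls$pos[i] <- p
  }
  lines <- variant_lines(calls)
  calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "lines") <- lines
  calls
}

#' Intersect two caller call sets
#'
#' A variant is retained iff an identical (chrom, pos, ref, alt) record is
#' present in both callers. Quality, depth and genotypes are taken from
#' caller A's record by default; `qual_from = "min"` takes the per-site
#' minimum of the two callers' qual and depth instead.
#'
#' @param calls_a,calls_b Call sets sorted by (chrom, pos), indels
#'   left-normalized (see [normalize_indels()]).
#' @param qual_from Either `"A"` (default) or `"min"`.
#' @return The consensus call set.
#' @export
intersect_callsets <- function(calls_a, calls_b, qual_from = c("A", "min")) {
  qual_from <- match.arg(qual_from)
  .check_sorted(calls_a, "caller A calls")
  .check_sorted(calls_b, "caller B calls")
  ka <- .variant_key(calls_a)
  kb <- .variant_key(calls_b)
  keep <- ka %in% kb
  out <- calls_a[keep, , drop = FALSE]
  if (qual_from == "min" && nrow(out) > 0) {
    idx <- match(.variant_key(out), kb)
    out$qual <- pmin(out$qual, calls_b$qual[idx])
    out$depth <- pmin(out$depth, calls_b$depth[idx])
  }
  rownames(out) <- NULL
  attr(out, "lines") <- variant_lines(calls_a)
  out
}

#' Apply per-site depth and quality filters
#'
#' A call passes iff `depth >= min_depth` AND `qual >= min_qual`; both
#' thresholds are inclusive. Depth is checked first, so a call failing both
#' is recorded as `fail_depth`.
#'
#' @param calls A call set.
#' @param min_depth Minimum read depth (default 5).
#' @param min_qual Minimum site quality (default 50).
#' @return The call set with a `filter_status` column in
#'   `{pass, fail_depth, fail_qual}`.
#' @export
apply_site_filters <- function(calls, min_depth = 5, min_qual = 50) {
  lines <- variant_lines(calls)
  status <- rep("pass", nrow(calls))
  status[calls$qual < min_qual] <- "fail_qual"
  status[calls$depth < min_depth] <- "fail_depth"  # depth checked first
  calls$filter_status <- status
  attr(calls, "lines") <- lines
  calls
}

#' Apply the SNP cluster-window filter
#'
#' Any SNP that is a member of a set of more than `max_in_window` SNPs
#' spanning at most `window_bp` consecutive bases on one chromosome is
#' marked `fail_cluster`, and every member of the offending cluster is
#' removed (the behavior of GATK's VariantFiltration cluster filter).
#' Indels do not populate the windows and are never marked by this rule.
#'
#' @param calls A call set sorted by (chrom, pos).
#' @param max_in_window Maximum SNPs allowed per window (default 2).
#' @param window_bp Window width in consecutive bases (default 10).
#' @return The call set with `filter_status` updated (existing non-pass
#'   statuses are preserved; only passing SNPs are re-examined).
#' @export
apply_cluster_filter <- function(calls, max_in_window = 2, window_bp = 10) {
  .check_sorted(calls, "calls")
  lines <- variant_lines(calls)
  if (is.null(calls$filter_status)) calls$filter_status <- "pass"
  snp <- is_snp(calls) & calls$filter_status == "pass"
  k <- max_in_window + 1L  # smallest violating cluster size
  for (chrom in unique(calls$chrom[snp])) {
    idx <- which(snp & calls$chrom == chrom)
    if (length(idx) < k) next
    pos <- calls$pos[idx]
    for (j in seq_len(length(idx) - k + 1L)) {
      if (pos[j + k - 1L] - pos[j] + 1L <= window_bp)
        calls$filter_status[idx[j:(j + k - 1L)]] <- "fail_cluster"
    }
  }
  attr(calls, "lines") <- lines
  calls
}

#' Run the full variant-retention pipeline
#'
#' Composes the three retention rules in fixed order: two-caller
#' intersection, then depth/quality site filters, then the SNP
#' cluster-window filter. Survivors have `filter_status == "pass"`; an audit
#' table records the count removed at every stage.
#'
#' @param calls_a,calls_b Call sets from the two callers.
#' @param min_depth,min_qual,max_in_window,window_bp Thresholds; defaults 5,
#'   50, 2 and 10.
#' @param qual_from See [intersect_callsets()].
#' @return A list: `variants` (passing calls), `all` (consensus calls with
#'   `filter_status`, non-consensus calls from caller A appended with status
#'   `fail_single_caller`), and `audit` (stage counts).
#' @export
filter_variants <- function(calls_a, calls_b, min_depth = 5, min_qual = 50,
                            max_in_window = 2, window_bp = 10,
                            qual_from = c("A", "min")) {
  lines <- variant_lines(calls_a)
  consensus <- intersect_callsets(calls_a, calls_b, qual_from = qual_from)
  n_in <- nrow(calls_a)
  n_consensus <- nrow(consensus)
  flagged <- apply_site_filters(consensus, min_depth = min_depth, min_qual = min_qual)
  n_site_fail <- sum(flagged$filter_status != "pass")
  flagged <- apply_cluster_filter(flagged, max_in_window = max_in_window,
                                  window_bp = window_bp)
  n_cluster_fail <- sum(flagged$filter_status == "fail_cluster")
  pass <- flagged[flagged$filter_status == "pass", , drop = FALSE]
  rownames(pass) <- NULL
  attr(pass, "lines") <- lines

  only_a <- calls_a[!(.variant_key(calls_a) %in% .variant_key(calls_b)), , drop = FALSE]
  if (nrow(only_a) > 0) only_a$filter_status <- "fail_single_caller"
  all_calls <- rbind(flagged, only_a)
  all_calls <- all_calls[order(all_calls$chrom, all_calls$pos), , drop = FALSE]
  rownames(all_calls) <- NULL
  attr(all_calls, "lines") <- lines

  audit <- data.frame(
    stage = c("input_caller_A", "consensus", "fail_depth_or_qual",
              "fail_cluster", "pass"),
    n = c(n_in, n_consensus, n_site_fail, n_cluster_fail, nrow(pass))
  )
  list(variants = pass, all = all_calls, audit = audit)
}
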