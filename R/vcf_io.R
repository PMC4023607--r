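# VCF input/output. Reading goes through vcfR; writing is a plain-text
# formatter for the fixed column layout this package emits (CHROM POS ID REF
# ALT QUAL FILTER INFO/DP FORMAT/GT + one sample column per line).

#' Read a multi-sample caller VCF into a call set
#'
#' Parses CHROM, POS, REF, ALT, QUAL, depth (INFO `DP`) and per-sample GT
#' fields. Genotypes map to `hom_ref` (all ref alleles), `hom_alt` (all alt),
#' `het` (mixed) or `missing` (`./.` or absent). Multi-allelic records are
#' split into biallelic rows sharing the site's QUAL and DP.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @return A call set (see [variant_calls()]).
#' @export
read_caller_vcf <- function(path) {
  if (!file.exists(path)) .stopf("VCF not found: %s", path)
  v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  lines <- setdiff(colnames(gt_raw), "FORMAT")
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  dp[is.na(dp)] <- 0L
  gt_only <- vcfR::extract.gt(v, element = "GT")

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      geno <- vapply(lines, function(l) {
        .decode_gt(gt_only[i, l], alt_index = ai)
      }, "")
      rows[[length(rows) + 1L]] <- c(
        list(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
             ref = fix$REF[i], alt = alts[ai],
             qual = suppressWarnings(as.numeric(fix$QUAL[i])),
             depth = dp[i]),
        as.list(geno)
      )
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df$qual[is.na(df$qual)] <- 0
  df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
  variant_calls(df, lines)
}

.decode_gt <- function(gt, alt_index = 1L) {
  if (is.na(gt) || gt %in% c("./.", ".", ".|.")) return("missing")
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".")) return("missing")
  al <- as.integer(al)
  hit <- al == alt_index
  if (all(hit)) "hom_alt" else if (any(hit)) "het" else "hom_ref"
}

#' Write a call set as VCF
#'
#' @param calls A call set (optionally with a `filter_status` column, which
#'   is emitted in the FILTER field; `pass` becomes `PASS`).
#' @param path Output path.
#' @param source_tag Value for the `##source` header line.
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(calls, path, source_tag = "txpoly") {
  lines <- variant_lines(calls)
  filt <- if (!is.null(calls$filter_status)) {
    ifelse(calls$filter_status == "pass", "PASS", calls$filter_status)
  } else rep(".", nrow(calls))
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=%s", source_tag),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", lines), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(calls)), function(i) {
    paste(c(calls$chrom[i], calls$pos[i], ".", calls$ref[i], calls$alt[i],
            format(calls$qual[i], scientific = FALSE, trim = TRUE), filt[i],
            sprintf("DP=%d", as.integer(calls$depth[i])), "GT",
            unname(gt_map[vapply(lines, function(l) calls[[l]][i], "")])),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
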