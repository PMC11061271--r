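# Two-sample VCF input/output for the IBD analysis. Reading goes through
# vcfR; only biallelic SNVs are retained, with a logged count of excluded
# records. Writing produces a minimal VCFv4.2 with GT:DP:GQ.

#' Read a two-sample VCF into a variant-sites table
#'
#' Parses a VCF (plain or gzipped) with [vcfR::read.vcfR()], extracts the
#' two named samples' genotypes (as allele dosages), FORMAT/DP, FORMAT/GQ
#' and FILTER, and returns sites sorted by (chrom, pos). Multiallelic and
#' non-SNV records are excluded with a message.
#'
#' @param path VCF path.
#' @param sample_a,sample_b Sample names; an error lists the available
#'   samples if one is missing.
#' @return A `variant_sites` data frame (`cm` is `NA`; see
#'   [interpolate_cm()]).
#' @seealso [filter_sites()], [call_ibd_segments()], [write_vcf_pair()]
#' @export
read_vcf_pair <- function(path, sample_a, sample_b) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  miss <- setdiff(c(sample_a, sample_b), samples)
  if (length(miss) > 0)
    stop("sample(s) ", paste(miss, collapse = ", "), " not in VCF; available: ",
         paste(samples, collapse = ", "))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) return(.empty_sites())
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  if (any(!snv))
    message(sum(!snv), " multiallelic/non-SNV record(s) excluded")
  dose <- function(gt) {
    a <- sub(":.*", "", gt)
    out <- rep(NA_integer_, length(a))
    out[a %in% c("0/0", "0|0")] <- 0L
    out[a %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[a %in% c("1/1", "1|1")] <- 2L
    out
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  ga <- v@gt[, sample_a]; gb <- v@gt[, sample_b]
  dpa <- num(vcfR::extract.gt(v, "DP")[, sample_a])
  dpb <- num(vcfR::extract.gt(v, "DP")[, sample_b])
  gqa <- num(vcfR::extract.gt(v, "GQ")[, sample_a])
  gqb <- num(vcfR::extract.gt(v, "GQ")[, sample_b])
  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = ref, alt = alt,
    g1 = dose(ga), g2 = dose(gb),
    filter = fix[, "FILTER"],
    dp1 = dpa, dp2 = dpb, gq1 = gqa, gq2 = gqb,
    cm = NA_real_, stringsAsFactors = FALSE)
  sites <- sites[snv, , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("variant_sites", "data.frame")
  sites
}

.empty_sites <- function() {
  s <- data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
                  alt = character(0), g1 = integer(0), g2 = integer(0),
                  filter = character(0), dp1 = numeric(0), dp2 = numeric(0),
                  gq1 = numeric(0), gq2 = numeric(0), cm = numeric(0),
                  stringsAsFactors = FALSE)
  class(s) <- c("variant_sites", "data.frame")
  s
}

#' @rdname read_vcf_pair
#' @param sites A `variant_sites` data frame to serialize.
#' @param sample_names Column names for the two samples.
#' @export
write_vcf_pair <- function(sites, path, sample_names = c("S1", "S2")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=LowQual,Description=\"Low quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")), con)
  gt_str <- function(g) ifelse(is.na(g), "./.",
                               c("0/0", "0/1", "1/1")[g + 1])
  if (nrow(sites) > 0) {
    rows <- paste(
      sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE), ".",
      sites$ref, sites$alt, ".", sites$filter, ".", "GT:DP:GQ",
      paste(gt_str(sites$g1), sites$dp1, sites$gq1, sep = ":"),
      paste(gt_str(sites$g2), sites$dp2, sites$gq2, sep = ":"),
      sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()] to serialize.
#' @param path Output path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
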