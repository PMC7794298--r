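#' Extract one variant from a VCF as additive genotypes
#'
#' Pulls the GT field of a single biallelic variant and codes it 0/1/2 as
#' the number of ALT alleles (phased or unphased). Missing genotypes
#' (`./.`) become `NA`, to be handled by the caller's complete-case or
#' imputation policy. Coordinates follow the VCF convention (1-based);
#' multiallelic records are refused.
#'
#' @param path VCF file (plain or bgzipped).
#' @param variant variant identifier: either an ID matching the VCF ID
#'   column, or `"chrom:pos"`.
#' @return named numeric vector of 0/1/2/`NA` per sample.
#' @export
extract_variant_from_vcf <- function(path, variant) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  hit <- if (grepl(":", variant, fixed = TRUE)) {
    parts <- strsplit(variant, ":", fixed = TRUE)[[1L]]
    which(fix[, "CHROM"] == parts[1L] & fix[, "POS"] == parts[2L])
  } else {
    which(fix[, "ID"] == variant)
  }
  if (!length(hit)) stop("variant '", variant, "' not found in ", path)
  if (length(hit) > 1L) stop("variant '", variant, "' matches multiple records")
  alt <- fix[hit, "ALT"]
  if (grepl(",", alt, fixed = TRUE))
    stop("variant '", variant, "' is multiallelic (ALT = ", alt, ")")
  gt <- vcfR::extract.gt(vcf, element = "GT")[hit, ]
  alleles <- strsplit(gt, "[/|]")
  g <- vapply(alleles, function(a) {
    if (any(is.na(a)) || any(a == ".")) return(NA_real_)
    sum(a == "1")
  }, numeric(1))
  setNames(g, colnames(vcf@gt)[-1L])
}
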