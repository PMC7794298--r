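#' Genome-wide pleiotropy scan over many SNPs
#'
#' Runs the pooled score test once per SNP column and applies a Bonferroni
#' threshold of `alpha / M` across the M SNPs. Degenerate SNPs (monomorphic,
#' singular V) are flagged, not fatal; their p-value is `NA`.
#'
#' @param genotypes n x M matrix of 0/1/2 genotypes, one column per SNP;
#'   column names become SNP ids.
#' @param phenotypes n x q binary phenotype matrix.
#' @param strata optional strata (as in [site_dataset()]) shared by all SNPs.
#' @param alpha family-wise level before Bonferroni division (default 0.05).
#' @param pseudo_inverse passed to [score_statistic()].
#' @return data frame with columns `snp_id`, `T`, `df`, `p`, `p_floored`,
#'   `significant`, `note`, plus attribute `"threshold"` (`alpha/M`).
#' @export
genomewide_scan <- function(genotypes, phenotypes, strata = NULL,
                            alpha = 0.05, pseudo_inverse = FALSE) {
  genotypes <- as.matrix(genotypes)
  M <- ncol(genotypes)
  if (M < 1L) stop("at least one SNP column is required")
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(M))
  threshold <- bonferroni_threshold(M, alpha)
  rows <- lapply(seq_len(M), function(m) {
    res <- tryCatch(
      pooled_test(site_dataset(genotypes[, m], phenotypes, strata = strata,
                               site_id = colnames(genotypes)[m]),
                  pseudo_inverse = pseudo_inverse),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(snp_id = colnames(genotypes)[m], T = NA_real_,
                 df = NA_integer_, p = NA_real_, p_floored = FALSE,
                 significant = FALSE, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(snp_id = colnames(genotypes)[m], T = res$statistic,
                 df = res$df, p = res$p_value, p_floored = res$p_floored,
                 significant = res$p_raw < threshold, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' The per-test level `alpha / M` controlling the family-wise error over M
#' tests (e.g. 0.05 over 6,106,952 genome-wide SNPs gives 8.19e-9).
#'
#' @param M number of tests.
#' @param alpha family-wise level.
#' @return scalar threshold.
#' @export
bonferroni_threshold <- function(M, alpha = 0.05) {
  if (M < 1) stop("M must be at least 1")
  alpha / M
}
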