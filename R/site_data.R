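#' Construct a site dataset
#'
#' Bundles one site's patient-level data: an additive genotype vector
#' (0/1/2 copies of the minor allele for one SNP), an n x q matrix of binary
#' phenotypes, and — when adjusting for categorical covariates — a stratum
#' label per subject and phenotype. Strata are opaque labels; callers cross
#' covariates (e.g. gender x age bin) into a single label, and the labels may
#' differ between phenotypes (e.g. a different age at diagnosis per disease).
#'
#' @param genotype integer vector of length n with values in \{0, 1, 2\}.
#' @param phenotypes n x q matrix or data frame of 0/1 phenotype indicators;
#'   column names become phenotype labels.
#' @param strata `NULL` for no adjustment (a single implicit stratum),
#'   a length-n vector of labels shared by all phenotypes, or an n x q matrix
#'   (or list of q length-n vectors) of phenotype-specific labels.
#' @param site_id label identifying the site in summary exchanges.
#' @param allow_fractional allow phenotype values inside (0, 1), as produced
#'   by deterministic prevalence imputation of missing values.
#'
#' @return An object of class `"site_dataset"`: a list with elements
#'   `site_id`, `genotype`, `phenotypes` (numeric matrix), `strata`
#'   (character n x q matrix), `n` and `q`.
#' @examples
#' d <- site_dataset(c(0, 1, 2), cbind(y1 = c(0, 1, 1)))
#' d$n
#' @export
site_dataset <- function(genotype, phenotypes, strata = NULL,
                         site_id = "site1", allow_fractional = FALSE) {
  genotype <- as.numeric(genotype)
  n <- length(genotype)
  if (n < 1L) stop("empty site: genotype vector has length 0")
  if (anyNA(genotype) || !all(genotype %in% c(0, 1, 2)))
    stop("genotype values must be 0, 1 or 2 (additive allele count)")

  phenotypes <- as.matrix(phenotypes)
  storage.mode(phenotypes) <- "double"
  if (nrow(phenotypes) != n)
    stop("phenotypes must have one row per genotyped subject (", n, ")")
  q <- ncol(phenotypes)
  if (q < 1L) stop("at least one phenotype column is required")
  if (anyNA(phenotypes))
    stop("missing phenotype values: apply complete-case filtering or impute_phenotypes() first")
  bad <- if (allow_fractional) {
    phenotypes < 0 | phenotypes > 1
  } else {
    phenotypes != 0 & phenotypes != 1
  }
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-binary phenotype value ", phenotypes[idx[1L], idx[2L]],
         " at row ", idx[1L], ", column ", idx[2L])
  }
  if (is.null(colnames(phenotypes)))
    colnames(phenotypes) <- paste0("y", seq_len(q))

  strata <- expand_strata(strata, n, q, colnames(phenotypes))

  structure(
    list(site_id = as.character(site_id), genotype = genotype,
         phenotypes = phenotypes, strata = strata, n = n, q = q),
    class = "site_dataset"
  )
}

# normalise the strata argument to a character n x q matrix
expand_strata <- function(strata, n, q, pheno_names) {
  if (is.null(strata)) {
    m <- matrix("ALL", n, q)
  } else if (is.list(strata) && !is.data.frame(strata)) {
    if (length(strata) != q)
      stop("strata list must have one element per phenotype (", q, ")")
    m <- vapply(strata, function(s) {
      if (length(s) != n) stop("each strata vector must have length ", n)
      as.character(s)
    }, character(n))
    m <- matrix(m, n, q)
  } else if (is.matrix(strata) || is.data.frame(strata)) {
    m <- as.matrix(strata)
    if (nrow(m) != n || ncol(m) != q)
      stop("strata matrix must be ", n, " x ", q)
    storage.mode(m) <- "character"
  } else {
    if (length(strata) != n) stop("strata vector must have length ", n)
    m <- matrix(as.character(strata), n, q)
  }
  if (anyNA(m)) stop("missing stratum labels are not allowed")
  colnames(m) <- pheno_names
  m
}

#' @export
print.site_dataset <- function(x, ...) {
  cat("Site dataset '", x$site_id, "': n = ", x$n, ", q = ", x$q,
      " phenotypes\n", sep = "")
  cat("  phenotypes:", paste(colnames(x$phenotypes), collapse = ", "), "\n")
  ns <- length(unique(as.vector(x$strata)))
  cat("  strata: ", ns, if (ns == 1L) " (unadjusted)" else "", "\n", sep = "")
  invisible(x)
}

#' Concatenate site datasets into one pooled dataset
#'
#' Row-binds the patient-level data of several sites, as a mega-analysis
#' would. Phenotype columns must agree across sites.
#'
#' @param sites list of [site_dataset()] objects.
#' @param site_id label for the combined dataset.
#' @return A single `"site_dataset"`.
#' @export
bind_sites <- function(sites, site_id = "pooled") {
  sites <- as_site_list(sites)
  q <- sites[[1L]]$q
  ph <- colnames(sites[[1L]]$phenotypes)
  for (s in sites) {
    if (s$q != q || !identical(colnames(s$phenotypes), ph))
      stop("sites disagree on phenotype columns")
  }
  site_dataset(
    genotype   = unlist(lapply(sites, `[[`, "genotype"), use.names = FALSE),
    phenotypes = do.call(rbind, lapply(sites, `[[`, "phenotypes")),
    strata     = do.call(rbind, lapply(sites, `[[`, "strata")),
    site_id    = site_id,
    allow_fractional = TRUE
  )
}

as_site_list <- function(sites) {
  if (inherits(sites, "site_dataset")) sites <- list(sites)
  if (!length(sites) || !all(vapply(sites, inherits, TRUE, "site_dataset")))
    stop("expected a site_dataset or a non-empty list of site_dataset objects")
  sites
}
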