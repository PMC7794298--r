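#' Read a site table into a site dataset
#'
#' Reads a delimited text file with one row per subject: a genotype column
#' (0/1/2), q binary phenotype columns and optional categorical covariate
#' columns. Covariates are cross-classified into a single stratum label per
#' subject; `per_phenotype_covariates` maps phenotypes to their own
#' covariate columns (e.g. a different age column per disease), yielding
#' phenotype-specific strata. Rows with missing phenotypes are dropped
#' (complete-case) unless `impute` is set.
#'
#' @param path delimited file with a header row.
#' @param phenotypes character vector of phenotype column names.
#' @param genotype_col name of the genotype column.
#' @param covariates character vector of covariate column names shared by
#'   all phenotypes, or `NULL` for no adjustment.
#' @param per_phenotype_covariates optional named list: for each phenotype,
#'   its covariate column names (overrides `covariates` for that phenotype).
#' @param site_id site label; defaults to the file name.
#' @param sep field separator; `"\t"` for TSV (default), `","` for CSV.
#' @param impute `NULL` for complete-case, or `"expected"` / `"bernoulli"`
#'   for [impute_phenotypes()].
#' @param seed seed for Bernoulli imputation.
#' @return a [site_dataset()].
#' @export
read_site_table <- function(path, phenotypes, genotype_col = "genotype",
                            covariates = NULL,
                            per_phenotype_covariates = NULL,
                            site_id = NULL, sep = "\t",
                            impute = NULL, seed = NULL) {
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c(genotype_col, phenotypes, covariates,
            unlist(per_phenotype_covariates, use.names = FALSE))
  missing_cols <- setdiff(unique(need), names(tab))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))

  g <- tab[[genotype_col]]
  bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)))
  if (length(bad))
    stop("invalid genotype value '", g[bad[1L]], "' at row ", bad[1L],
         " of column '", genotype_col, "'")
  Y <- as.matrix(tab[phenotypes])
  bad <- which(!is.na(Y) & Y != 0 & Y != 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-binary phenotype value '", Y[bad[1L, 1L], bad[1L, 2L]],
         "' at row ", bad[1L, 1L], " of column '", phenotypes[bad[1L, 2L]], "'")

  if (!is.null(impute)) {
    Y <- impute_phenotypes(Y, mode = impute, seed = seed)
  }
  keep <- !is.na(g) & rowSums(is.na(Y)) == 0L
  tab <- tab[keep, , drop = FALSE]
  g <- g[keep]
  Y <- Y[keep, , drop = FALSE]
  if (!nrow(Y)) stop("empty site: no complete rows in ", path)

  strata <- vapply(phenotypes, function(ph) {
    cols <- if (!is.null(per_phenotype_covariates) &&
                ph %in% names(per_phenotype_covariates)) {
      per_phenotype_covariates[[ph]]
    } else covariates
    if (is.null(cols)) rep("ALL", nrow(tab))
    else do.call(paste, c(lapply(tab[cols], as.character), sep = "|"))
  }, character(nrow(tab)))
  strata <- matrix(strata, nrow(tab), length(phenotypes))

  site_dataset(g, Y, strata = strata,
               site_id = site_id %||% basename(path),
               allow_fractional = identical(impute, "expected"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a site dataset to a delimited file
#'
#' Inverse of [read_site_table()] for unadjusted or shared-strata datasets;
#' round-trips at full double precision.
#'
#' @param data a [site_dataset()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_site_table <- function(data, path, sep = "\t") {
  stopifnot(inherits(data, "site_dataset"))
  tab <- data.frame(sample_id = seq_len(data$n), genotype = data$genotype,
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(data$phenotypes))
  if (length(unique(as.vector(data$strata))) > 1L)
    tab$stratum <- data$strata[, 1L]
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Impute missing phenotype values from disease prevalence
#'
#' Fills `NA` phenotype cells using the observed per-phenotype prevalence:
#' `"bernoulli"` draws a 0/1 value with that probability (seeded, stays
#' binary); `"expected"` fills deterministically with the prevalence itself
#' (fractional; accepted by [site_dataset()] with
#' `allow_fractional = TRUE`).
#'
#' @param Y phenotype matrix with possible `NA`s.
#' @param mode `"bernoulli"` or `"expected"`.
#' @param seed required for `"bernoulli"`.
#' @return imputed matrix.
#' @export
impute_phenotypes <- function(Y, mode = c("bernoulli", "expected"),
                              seed = NULL) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  if (mode == "bernoulli") {
    if (is.null(seed)) stop("bernoulli imputation requires a seed")
    set.seed(seed)
  }
  for (j in seq_len(ncol(Y))) {
    na <- is.na(Y[, j])
    if (!any(na)) next
    prev <- mean(Y[!na, j])
    if (is.nan(prev)) stop("phenotype column ", j, " is entirely missing")
    Y[na, j] <- if (mode == "expected") prev else rbinom(sum(na), 1, prev)
  }
  Y
}

# ---- JSON summary exchange -------------------------------------------------

#' Serialize summary-exchange documents to JSON
#'
#' Round-1 and round-2 summaries (and the pooled reference) are exchanged
#' between sites and the central analyst as JSON documents carrying a schema
#' version, the site id, q, the stratum vocabulary and the numeric payload
#' (V as a full row-major array). Serialization is lossless at IEEE double
#' precision.
#'
#' @param x a `stage1_summary`, `pooled_reference` or `stage2_summary`.
#' @param path optional file to write; otherwise the JSON string is
#'   returned.
#' @return JSON string (invisibly the path when writing to file).
#' @export
summary_to_json <- function(x, path = NULL) {
  doc <- if (inherits(x, "stage1_summary")) {
    list(schema = "sumshare-stage1/1", site_id = x$site_id, n = x$n,
         q = x$q, phenotypes = x$phenotypes, cells = x$cells)
  } else if (inherits(x, "pooled_reference")) {
    list(schema = "sumshare-reference/1", n = x$n, q = x$q,
         phenotypes = x$phenotypes, cells = x$cells)
  } else if (inherits(x, "stage2_summary")) {
    list(schema = "sumshare-stage2/1", site_id = x$site_id, q = x$q,
         phenotypes = x$phenotypes, S = unname(x$S),
         V_row_major = as.vector(t(x$V)))
  } else stop("unsupported object of class ", class(x)[1L])
  # I(17) = 17 significant digits, enough to round-trip any IEEE double
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' @rdname summary_to_json
#' @param json JSON string or path to a JSON file.
#' @export
summary_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  doc <- jsonlite::fromJSON(json)
  switch(doc$schema,
    "sumshare-stage1/1" = structure(
      list(site_id = doc$site_id, n = doc$n, q = doc$q,
           phenotypes = doc$phenotypes,
           cells = as.data.frame(doc$cells)),
      class = "stage1_summary"),
    "sumshare-reference/1" = structure(
      list(n = doc$n, q = doc$q, phenotypes = doc$phenotypes,
           cells = as.data.frame(doc$cells)),
      class = "pooled_reference"),
    "sumshare-stage2/1" = {
      V <- matrix(doc$V_row_major, doc$q, doc$q, byrow = TRUE,
                  dimnames = list(doc$phenotypes, doc$phenotypes))
      structure(
        list(site_id = doc$site_id, q = doc$q, phenotypes = doc$phenotypes,
             S = setNames(doc$S, doc$phenotypes), V = V),
        class = "stage2_summary")
    },
    stop("unknown schema '", doc$schema, "'")
  )
}
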