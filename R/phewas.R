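#' Logistic regression of one phenotype on the SNP
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a binary
#' phenotype on the additive genotype, optionally adjusting for covariates.
#' Returns the Wald estimate, standard error and p-value for the genotype
#' term. Complete separation or non-convergence is flagged rather than
#' fatal, so small sites with rare SNPs can still enter a meta-analysis
#' (they are excluded there).
#'
#' @param y binary outcome vector.
#' @param x additive genotype vector (0/1/2).
#' @param covariates optional data frame of covariates; categorical columns
#'   enter as factors.
#' @param phenotype label carried through to the result.
#' @return list of class `"association_fit"`: `phenotype`, `beta`, `se`,
#'   `p`, `converged`, `message`.
#' @export
logistic_fit <- function(y, x, covariates = NULL, phenotype = "y") {
  y <- as.numeric(y)
  x <- as.numeric(x)
  if (length(unique(y)) < 2L) stop("degenerate outcome: phenotype is constant")
  if (length(unique(x)) < 2L) stop("constant predictor: genotype has no variation")
  df <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      if (length(unique(covariates[[nm]])) < 2L) next  # constant, drop
      df[[nm]] <- if (is.numeric(covariates[[nm]])) covariates[[nm]]
                  else factor(covariates[[nm]])
    }
  }
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial(), control = list(epsilon = 1e-10))
  )
  est <- coef(fit)[".x"]
  se <- sqrt(diag(vcov(fit))[".x"])
  # huge |beta| or se signals separation: the Wald quantities are meaningless
  converged <- isTRUE(fit$converged) && is.finite(est) && is.finite(se) &&
    abs(est) < 15 && se < 50
  p <- if (converged) 2 * pnorm(-abs(est / se)) else NA_real_
  structure(
    list(phenotype = phenotype, beta = unname(est), se = unname(se),
         p = unname(p), converged = converged,
         message = if (!converged) "non-convergence or separation"),
    class = "association_fit"
  )
}

#' Bonferroni minimum-p decision over phenotypes
#'
#' The PheWAS call: each per-phenotype p-value is Bonferroni-adjusted by the
#' number of phenotypes, and the SNP is declared pleiotropy-relevant when the
#' minimum adjusted p-value falls below `alpha`.
#'
#' @param pvals per-phenotype p-values in (0, 1]; `NA` entries (failed fits)
#'   are ignored in the minimum but still count towards q.
#' @param alpha significance level.
#' @param q number of tests adjusted for; defaults to `length(pvals)`.
#' @return list of class `"phewas_decision"`: `adjusted` (per-phenotype),
#'   `min_adjusted`, `significant`, `alpha`.
#' @export
phewas_decision <- function(pvals, alpha = 0.05, q = length(pvals)) {
  if (!length(pvals)) stop("empty p-value vector")
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) stop("p-values must lie in (0, 1]")
  adjusted <- pmin(1, q * pvals)
  min_adjusted <- if (any(ok)) min(adjusted[ok]) else NA_real_
  structure(
    list(adjusted = adjusted, min_adjusted = min_adjusted,
         significant = isTRUE(min_adjusted < alpha), alpha = alpha),
    class = "phewas_decision"
  )
}

#' Inverse-variance-weighted meta-analysis of per-site fits
#'
#' Combines per-site log-odds ratios for one phenotype with weights
#' \eqn{w_k = 1/se_k^2}: pooled beta \eqn{\sum w_k \beta_k / \sum w_k},
#' pooled se \eqn{(\sum w_k)^{-1/2}}, Wald p from the normal reference.
#' Non-converged fits are excluded.
#'
#' @param fits list of [logistic_fit()] results for one phenotype.
#' @return An `"association_fit"` for the pooled estimate.
#' @export
ivw_meta <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop("all per-site fits failed to converge")
  beta <- vapply(fits, `[[`, 0, "beta")
  w <- 1 / vapply(fits, `[[`, 0, "se")^2
  mb <- sum(w * beta) / sum(w)
  mse <- 1 / sqrt(sum(w))
  structure(
    list(phenotype = fits[[1L]]$phenotype, beta = mb, se = mse,
         p = 2 * pnorm(-abs(mb / mse)), converged = TRUE, message = NULL,
         n_sites = length(fits)),
    class = "association_fit"
  )
}

phewas_covariates <- function(data, j, use_strata) {
  if (!use_strata) return(NULL)
  s <- data$strata[, j]
  if (length(unique(s)) < 2L) return(NULL)
  data.frame(stratum = s)
}

fit_site_phenotypes <- function(data, use_strata) {
  lapply(seq_len(data$q), function(j) {
    tryCatch(
      logistic_fit(data$phenotypes[, j], data$genotype,
                   covariates = phewas_covariates(data, j, use_strata),
                   phenotype = colnames(data$phenotypes)[j]),
      error = function(e) structure(
        list(phenotype = colnames(data$phenotypes)[j], beta = NA_real_,
             se = NA_real_, p = NA_real_, converged = FALSE,
             message = conditionMessage(e)),
        class = "association_fit")
    )
  })
}

phewas_result <- function(fits, alpha, mode) {
  tab <- data.frame(
    phenotype = vapply(fits, `[[`, "", "phenotype"),
    beta = vapply(fits, `[[`, 0, "beta"),
    se = vapply(fits, `[[`, 0, "se"),
    p = vapply(fits, `[[`, 0, "p"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    row.names = NULL
  )
  dec <- phewas_decision(tab$p, alpha = alpha, q = nrow(tab))
  tab$p_adjusted <- dec$adjusted
  structure(
    list(table = tab, min_adjusted = dec$min_adjusted,
         significant = dec$significant, alpha = alpha, mode = mode),
    class = "phewas"
  )
}

#' PheWAS baselines: single-site, meta-analysis and mega-analysis
#'
#' The comparator to the joint score test: a separate logistic regression of
#' each phenotype on the SNP, combined across sites either by
#' inverse-variance-weighted meta-analysis of the per-site coefficients
#' (`phewas_meta`) or by pooling the individual-level rows and fitting once
#' (`phewas_mega`). Significance is the Bonferroni minimum-p rule of
#' [phewas_decision()].
#'
#' @param sites a [site_dataset()] or list of them.
#' @param alpha significance level for the Bonferroni decision.
#' @param adjust_strata include each dataset's stratum labels as a
#'   categorical covariate in the per-phenotype fits.
#' @return object of class `"phewas"`: per-phenotype table
#'   (beta, se, p, converged, p_adjusted), `min_adjusted`, `significant`.
#' @export
phewas_mega <- function(sites, alpha = 0.05, adjust_strata = FALSE) {
  data <- bind_sites(as_site_list(sites))
  fits <- fit_site_phenotypes(data, adjust_strata)
  phewas_result(fits, alpha, "mega")
}

#' @rdname phewas_mega
#' @export
phewas_meta <- function(sites, alpha = 0.05, adjust_strata = FALSE) {
  sites <- as_site_list(sites)
  per_site <- lapply(sites, fit_site_phenotypes, use_strata = adjust_strata)
  q <- sites[[1L]]$q
  fits <- lapply(seq_len(q), function(j) {
    tryCatch(ivw_meta(lapply(per_site, `[[`, j)),
             error = function(e) structure(
               list(phenotype = colnames(sites[[1L]]$phenotypes)[j],
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    converged = FALSE, message = conditionMessage(e)),
               class = "association_fit"))
  })
  phewas_result(fits, alpha, "meta")
}

#' @rdname phewas_mega
#' @export
phewas_single <- function(sites, alpha = 0.05, adjust_strata = FALSE) {
  sites <- as_site_list(sites)
  if (length(sites) != 1L) stop("phewas_single expects exactly one site")
  fits <- fit_site_phenotypes(sites[[1L]], adjust_strata)
  phewas_result(fits, alpha, "single")
}

#' @export
print.phewas <- function(x, ...) {
  cat("PheWAS (", x$mode, "): ", nrow(x$table), " phenotypes, alpha = ",
      x$alpha, "\n", sep = "")
  print(x$table, digits = 4)
  cat("minimum Bonferroni-adjusted p = ", format(x$min_adjusted, digits = 4),
      if (x$significant) "  -> significant" else "  -> not significant",
      "\n", sep = "")
  invisible(x)
}
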