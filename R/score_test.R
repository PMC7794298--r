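#' Score statistic from pooled score and variance
#'
#' Forms the quadratic form \eqn{T = S V^{-1} S^\top}. `V` must be symmetric
#' positive definite; a singular `V` (monomorphic SNP, constant phenotype, or
#' perfectly collinear phenotypes) is an error by default. With
#' `pseudo_inverse = TRUE` a Moore-Penrose inverse is used instead and the
#' degrees of freedom are reduced to the rank of `V`, which is flagged on the
#' result: silent pseudo-inversion would change the null reference
#' distribution, so it is opt-in.
#'
#' @param S numeric score vector of length q.
#' @param V q x q symmetric variance matrix of `S`.
#' @param pseudo_inverse use the Moore-Penrose inverse when `V` is rank
#'   deficient, with `df = rank(V)`.
#' @param tol relative eigenvalue tolerance used to call rank deficiency.
#' @return list with `statistic`, `df` and `rank_deficient`.
#' @examples
#' score_statistic(1, matrix(0.5))$statistic  # 2
#' @export
score_statistic <- function(S, V, pseudo_inverse = FALSE, tol = 1e-10) {
  S <- as.numeric(S)
  V <- as.matrix(V)
  q <- length(S)
  if (!all(dim(V) == q)) stop("V must be ", q, " x ", q)
  if (max(abs(V - t(V))) > tol * max(1, max(abs(V))))
    stop("V must be symmetric")
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  thresh <- tol * max(abs(ev$values), 0)
  keep <- ev$values > thresh
  rank_deficient <- sum(keep) < q
  if (rank_deficient && !pseudo_inverse) {
    dead <- which(diag(V) <= thresh)
    hint <- if (length(dead)) {
      paste0(" (zero score variance for component ",
             paste(dead, collapse = ", "),
             ": constant phenotype or monomorphic SNP)")
    } else {
      paste0(" (", sum(!keep), " collinear score direction",
             if (sum(!keep) > 1L) "s", ")")
    }
    stop("V is singular", hint,
         "; rerun with pseudo_inverse = TRUE to test on the non-degenerate subspace")
  }
  if (!any(keep)) {
    return(list(statistic = 0, df = 0L, rank_deficient = TRUE))
  }
  z <- crossprod(ev$vectors[, keep, drop = FALSE], S)
  statistic <- sum(z^2 / ev$values[keep])
  list(statistic = as.numeric(statistic), df = sum(keep),
       rank_deficient = rank_deficient)
}

#' P-value of the score statistic
#'
#' Refers T to the chi-squared distribution with `df` degrees of freedom:
#' \eqn{p = 1 - \Psi_q(T)}. Values below the double-precision floor
#' 2.22e-16 are reported at the floor and flagged; the raw value is
#' returned alongside.
#'
#' @param statistic nonnegative score statistic.
#' @param df degrees of freedom (number of phenotypes, or rank of V under
#'   pseudo-inversion).
#' @return list with `p_value` (floored), `p_raw`, `p_floored` flag.
#' @export
pvalue_from_statistic <- function(statistic, df) {
  if (length(statistic) != 1L || is.na(statistic) || statistic < 0)
    stop("statistic must be a single nonnegative number")
  if (df < 1) stop("degrees of freedom must be at least 1")
  p_raw <- pchisq(statistic, df = df, lower.tail = FALSE)
  floored <- p_raw < P_FLOOR
  list(p_value = if (floored) P_FLOOR else p_raw,
       p_raw = p_raw, p_floored = floored)
}

#' Distributed or pooled pleiotropy score test
#'
#' The main entry point. Tests H0: the SNP is associated with none of the q
#' binary phenotypes, against the alternative that it is associated with at
#' least one, using the composite-likelihood score statistic
#' \eqn{T = S V^{-1} S^\top \sim \chi^2_q} under H0. With
#' `method = "distributed"` the computation runs the two-round
#' summary-exchange protocol across the sites; with `method = "pooled"` the
#' sites are concatenated and analysed as one dataset. The two routes give
#' identical results (the protocol is lossless), so `"pooled"` mainly serves
#' as the oracle in verification.
#'
#' Categorical covariate adjustment is encoded in the datasets' stratum
#' labels: scores are centered within covariate strata, so the null fitted
#' values are stratum-specific prevalences.
#'
#' @param sites a [site_dataset()] or list of them (one per site).
#' @param method `"distributed"` (two-round protocol) or `"pooled"`.
#' @param pseudo_inverse passed to [score_statistic()].
#' @return An object of class `"sumshare"`: list with `statistic`, `df`,
#'   `p_value`, `p_raw`, `p_floored`, `rank_deficient`, `S`, `V`, `n`, `q`,
#'   `K`, `method`, `sites` (site ids and sizes) and `stage2` (per-site
#'   contributions, distributed method only).
#' @examples
#' d <- site_dataset(c(0, 1, 2, 1), cbind(y = c(0, 1, 1, 0)))
#' fit <- sumshare(d)
#' fit$statistic  # 2
#' @export
sumshare <- function(sites, method = c("distributed", "pooled"),
                     pseudo_inverse = FALSE) {
  method <- match.arg(method)
  sites <- as_site_list(sites)
  site_tab <- data.frame(
    site_id = vapply(sites, `[[`, "", "site_id"),
    n = vapply(sites, `[[`, 0L, "n")
  )
  if (method == "pooled" && length(sites) > 1L) {
    sites <- list(bind_sites(sites))
  }
  stage1 <- lapply(sites, site_stage1)
  ref <- pool_stage1(stage1)
  stage2 <- lapply(sites, site_stage2, ref = ref)
  pooled <- pool_stage2(stage2)
  st <- score_statistic(pooled$S, pooled$V, pseudo_inverse = pseudo_inverse)
  pv <- pvalue_from_statistic(st$statistic, st$df)
  structure(
    list(statistic = st$statistic, df = st$df,
         p_value = pv$p_value, p_raw = pv$p_raw, p_floored = pv$p_floored,
         rank_deficient = st$rank_deficient,
         S = pooled$S, V = pooled$V,
         n = ref$n, q = ref$q, K = nrow(site_tab),
         method = method, sites = site_tab,
         stage2 = if (method == "distributed") stage2),
    class = "sumshare"
  )
}

#' @rdname sumshare
#' @export
distributed_test <- function(sites, pseudo_inverse = FALSE) {
  sumshare(sites, method = "distributed", pseudo_inverse = pseudo_inverse)
}

#' @param combined a single [site_dataset()] (or list of sites to
#'   concatenate) analysed as pooled individual-level data.
#' @rdname sumshare
#' @export
pooled_test <- function(combined, pseudo_inverse = FALSE) {
  sumshare(combined, method = "pooled", pseudo_inverse = pseudo_inverse)
}

format_p <- function(x) {
  if (x$p_floored) paste0("< ", format(P_FLOOR)) else format(x$p_value, digits = 4)
}

#' @export
print.sumshare <- function(x, ...) {
  cat("Pleiotropy score test (", x$method, ")\n", sep = "")
  cat("  sites: ", x$K, "   subjects: ", x$n, "   phenotypes: ", x$q, "\n", sep = "")
  cat("  T = ", format(x$statistic, digits = 6), " on ", x$df,
      " df,  p = ", format_p(x), "\n", sep = "")
  if (x$rank_deficient)
    cat("  note: V rank deficient; df reduced to rank(V)\n")
  invisible(x)
}

#' @export
summary.sumshare <- function(object, ...) {
  z <- object$S / sqrt(pmax(diag(object$V), .Machine$double.eps))
  per_pheno <- data.frame(
    phenotype = names(object$S),
    score = as.numeric(object$S),
    variance = diag(object$V),
    z = as.numeric(z),
    row.names = NULL
  )
  out <- list(test = object, per_phenotype = per_pheno)
  class(out) <- "summary.sumshare"
  out
}

#' @export
print.summary.sumshare <- function(x, ...) {
  print(x$test)
  cat("\nPer-phenotype score components (marginal z = S_j / sqrt(V_jj)):\n")
  print(x$per_phenotype, digits = 4)
  invisible(x)
}

#' Plot per-phenotype score contributions
#'
#' Barplot of the marginal standardized scores \eqn{S_j / \sqrt{V_{jj}}},
#' a diagnostic for which phenotypes drive the joint statistic. The joint
#' test accounts for their correlation; the bars do not.
#'
#' @param x a `"sumshare"` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sumshare <- function(x, ...) {
  z <- x$S / sqrt(pmax(diag(x$V), .Machine$double.eps))
  graphics::barplot(z, names.arg = names(x$S), las = 2,
                    ylab = "standardized score", ...)
  graphics::abline(h = 0)
  invisible(x)
}
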