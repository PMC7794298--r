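#' Round 1: per-site counts and sums
#'
#' Computes the first-round summary a site shares with the central analyst:
#' for every phenotype and covariate stratum, the subject count, the
#' phenotype sum and the genotype sum inside that stratum. In the unadjusted
#' case there is a single stratum and the summary reduces to
#' \eqn{n_k, n_k \bar y_k, n_k \bar x_k}. No patient-level rows are exposed.
#'
#' @param data a [site_dataset()].
#' @return An object of class `"stage1_summary"`: list with `site_id`, `n`,
#'   `q`, `phenotypes` and a data frame `cells` with columns
#'   `phenotype`, `stratum`, `n`, `sum_y`, `sum_x`.
#' @export
site_stage1 <- function(data) {
  stopifnot(inherits(data, "site_dataset"))
  ph <- colnames(data$phenotypes)
  cells <- do.call(rbind, lapply(seq_len(data$q), function(j) {
    s <- data$strata[, j]
    agg_n <- tapply(rep(1, data$n), s, sum)
    agg_y <- tapply(data$phenotypes[, j], s, sum)
    agg_x <- tapply(data$genotype, s, sum)
    data.frame(phenotype = ph[j], stratum = names(agg_n),
               n = as.numeric(agg_n), sum_y = as.numeric(agg_y),
               sum_x = as.numeric(agg_x), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(site_id = data$site_id, n = data$n, q = data$q,
         phenotypes = ph, cells = cells),
    class = "stage1_summary"
  )
}

#' Central analyst: pool round-1 summaries into reference means
#'
#' Adds up the per-site counts and sums and returns, for every phenotype and
#' stratum, the pooled phenotype mean (the null fitted value; the logistic
#' intercept profiled out under the null is its logit) and the pooled
#' genotype mean. These are the only quantities returned to the sites.
#'
#' @param summaries list of [site_stage1()] results (or a single one).
#' @return An object of class `"pooled_reference"`: list with `n`, `q`,
#'   `phenotypes` and data frame `cells` with columns `phenotype`, `stratum`,
#'   `n`, `p` (pooled phenotype mean) and `xbar` (pooled genotype mean).
#' @export
pool_stage1 <- function(summaries) {
  if (inherits(summaries, "stage1_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop("no stage-1 summaries supplied")
  q <- summaries[[1L]]$q
  ph <- summaries[[1L]]$phenotypes
  for (s in summaries) {
    if (!inherits(s, "stage1_summary")) stop("expected stage1_summary objects")
    if (s$q != q || !identical(s$phenotypes, ph))
      stop("inconsistent phenotype set across stage-1 summaries")
  }
  all_cells <- do.call(rbind, lapply(summaries, `[[`, "cells"))
  key <- interaction(all_cells$phenotype, all_cells$stratum, drop = TRUE, sep = "\r")
  tot <- data.frame(
    n     = as.numeric(tapply(all_cells$n, key, sum)),
    sum_y = as.numeric(tapply(all_cells$sum_y, key, sum)),
    sum_x = as.numeric(tapply(all_cells$sum_x, key, sum))
  )
  ks <- strsplit(levels(key), "\r", fixed = TRUE)
  cells <- data.frame(
    phenotype = vapply(ks, `[`, "", 1L),
    stratum   = vapply(ks, `[`, "", 2L),
    n = tot$n, p = tot$sum_y / tot$n, xbar = tot$sum_x / tot$n,
    stringsAsFactors = FALSE
  )
  if (any(tot$n == 0)) stop("a referenced stratum has zero pooled count")
  structure(
    list(n = sum(vapply(summaries, `[[`, 0, "n")), q = q,
         phenotypes = ph, cells = cells),
    class = "pooled_reference"
  )
}

# lookup tables p_{j,s} and xbar_{j,s} for one phenotype
ref_maps <- function(ref, phenotype) {
  cells <- ref$cells[ref$cells$phenotype == phenotype, , drop = FALSE]
  list(p = setNames(cells$p, cells$stratum),
       xbar = setNames(cells$xbar, cells$stratum))
}

#' Round 2: per-site score and variance contributions
#'
#' Given the pooled reference means, each site computes its score
#' contribution \eqn{S_k} (length q) and variance contribution \eqn{V_k}
#' (q x q). Per subject i the component for phenotype j is the
#' stratum-centered score
#' \deqn{u_{ij} = (x_i - \bar x_{j, s_j(i)})\,(y_{ij} - p_{j, s_j(i)}),}
#' with \eqn{S_k = \sum_i u_i} and \eqn{V_k = \sum_i u_i u_i^\top}. With a
#' single stratum this is the classic centered score
#' \eqn{\sum_i (x_i-\bar x)(y_i-\bar y)} whose sum over sites equals the
#' uncentered pooled score \eqn{\sum (x y - x \bar y)} exactly, since the
#' pooled phenotype residuals sum to zero.
#'
#' @param data a [site_dataset()].
#' @param ref the [pool_stage1()] reference; must cover every stratum
#'   present in `data`.
#' @return An object of class `"stage2_summary"`: list with `site_id`, `q`,
#'   `phenotypes`, `S` (length-q vector) and `V` (q x q symmetric PSD matrix).
#' @export
site_stage2 <- function(data, ref) {
  stopifnot(inherits(data, "site_dataset"), inherits(ref, "pooled_reference"))
  if (data$q != ref$q || !identical(colnames(data$phenotypes), ref$phenotypes))
    stop("site and reference disagree on phenotypes")
  U <- matrix(0, data$n, data$q)
  for (j in seq_len(data$q)) {
    maps <- ref_maps(ref, ref$phenotypes[j])
    s <- data$strata[, j]
    miss <- setdiff(unique(s), names(maps$p))
    if (length(miss))
      stop("stratum '", miss[1L], "' of phenotype '", ref$phenotypes[j],
           "' is missing from the pooled reference")
    U[, j] <- (data$genotype - maps$xbar[s]) * (data$phenotypes[, j] - maps$p[s])
  }
  V <- crossprod(U)
  dimnames(V) <- list(ref$phenotypes, ref$phenotypes)
  structure(
    list(site_id = data$site_id, q = data$q, phenotypes = ref$phenotypes,
         S = setNames(colSums(U), ref$phenotypes), V = V),
    class = "stage2_summary"
  )
}

#' Central analyst: pool round-2 contributions
#'
#' Element-wise sums: \eqn{S = \sum_k S_k}, \eqn{V = \sum_k V_k}.
#'
#' @param summaries list of [site_stage2()] results (or a single one).
#' @return list with components `S` (length q) and `V` (q x q).
#' @export
pool_stage2 <- function(summaries) {
  if (inherits(summaries, "stage2_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop("no stage-2 summaries supplied")
  q <- summaries[[1L]]$q
  for (s in summaries) {
    if (!inherits(s, "stage2_summary")) stop("expected stage2_summary objects")
    if (length(s$S) != q || !all(dim(s$V) == q))
      stop("dimension mismatch across stage-2 summaries")
  }
  S <- Reduce(`+`, lapply(summaries, `[[`, "S"))
  V <- Reduce(`+`, lapply(summaries, `[[`, "V"))
  list(S = S, V = V)
}
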