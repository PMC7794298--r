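#' @keywords internal
# per-rep substreams: a master seed yields one integer seed per repetition,
# so every method arm regenerates identical data within a repetition
rep_seeds <- function(seed, reps) {
  set.seed(seed)
  sample.int(2147483646L, reps)
}

method_labels <- c("sumshare-distributed", "sumshare-pooled",
                   "phewas-meta", "phewas-mega")

# apply one method to a simulated multi-site dataset; returns TRUE on rejection
apply_method <- function(method, sites, alpha) {
  adjust <- length(unique(as.vector(sites[[1L]]$strata))) > 1L
  switch(method,
    "sumshare-distributed" = sumshare(sites, "distributed")$p_raw < alpha,
    "sumshare-pooled"      = sumshare(sites, "pooled")$p_raw < alpha,
    "phewas-meta"          = phewas_meta(sites, alpha, adjust_strata = adjust)$significant,
    "phewas-mega"          = phewas_mega(sites, alpha, adjust_strata = adjust)$significant,
    stop("unknown method '", method, "'")
  )
}

power_row <- function(method, rejections, reps, alpha, scenario) {
  rate <- rejections / reps
  data.frame(
    method = method, pattern = scenario$pattern, beta_ref = scenario$beta_ref,
    correlated = !is.null(scenario$correlation), reps = reps, alpha = alpha,
    rejection_rate = rate, monte_carlo_se = sqrt(rate * (1 - rate) / reps),
    stringsAsFactors = FALSE
  )
}

#' Monte-Carlo power (or type-I error) of one method
#'
#' Simulates `reps` independent multi-site studies under the scenario,
#' applies the method at level `alpha`, and reports the rejection rate with
#' its binomial Monte-Carlo standard error. Under `pattern = "null"` the
#' rate estimates the type-I error. Per-repetition seeds are derived
#' deterministically from `seed`.
#'
#' @param method one of `"sumshare-distributed"`, `"sumshare-pooled"`,
#'   `"phewas-meta"`, `"phewas-mega"`.
#' @param scenario a [sim_scenario()] (its own seed field is ignored here).
#' @param reps number of repetitions.
#' @param alpha significance level.
#' @param seed master seed for the repetition substreams.
#' @return one-row data frame: method, pattern, beta_ref, correlated, reps,
#'   alpha, rejection_rate, monte_carlo_se.
#' @export
estimate_power <- function(method, scenario, reps = 200, alpha = 0.05,
                           seed = 1) {
  if (reps < 1) stop("reps must be at least 1")
  if (!method %in% method_labels) stop("unknown method '", method, "'")
  seeds <- rep_seeds(seed, reps)
  rej <- 0L
  for (r in seq_len(reps)) {
    scenario$seed <- seeds[r]
    sites <- simulate_multisite(scenario)
    rej <- rej + apply_method(method, sites, alpha)
  }
  power_row(method, rej, reps, alpha, scenario)
}

#' Paired power comparison across methods
#'
#' Runs several methods over a grid of scenarios with a paired design:
#' within each repetition all methods see the same simulated datasets, so
#' method differences are not confounded by simulation noise.
#'
#' @param scenarios a [sim_scenario()] or list of them.
#' @param methods character vector of method labels.
#' @param reps repetitions per scenario.
#' @param alpha significance level.
#' @param seed master seed.
#' @param keep_reps attach the reps x methods logical rejection matrix per
#'   scenario (attribute `"rejections"`, a list), enabling paired
#'   standard errors for method differences.
#' @return long-format data frame of power rows plus a `rejections` count
#'   column (identical seeds across methods make counts comparable).
#' @export
compare_methods <- function(scenarios, methods = method_labels,
                            reps = 200, alpha = 0.05, seed = 1,
                            keep_reps = FALSE) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  out <- list()
  rejmats <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    seeds <- rep_seeds(seed, reps)
    rejmat <- matrix(FALSE, reps, length(methods),
                     dimnames = list(NULL, methods))
    for (r in seq_len(reps)) {
      sc$seed <- seeds[r]
      sites <- simulate_multisite(sc)
      for (m in methods) rejmat[r, m] <- apply_method(m, sites, alpha)
    }
    for (m in methods) {
      row <- power_row(m, sum(rejmat[, m]), reps, alpha, sc)
      row$scenario <- si
      row$rejections <- sum(rejmat[, m])
      out[[length(out) + 1L]] <- row
    }
    rejmats[[si]] <- rejmat
  }
  res <- do.call(rbind, out)
  if (keep_reps) attr(res, "rejections") <- rejmats
  res
}

#' Verify losslessness of the distributed protocol
#'
#' Simulates `n_datasets` multi-site studies and compares the distributed
#' p-value with the pooled individual-level p-value on each; returns the
#' maximum absolute discrepancy (zero up to floating-point summation order,
#' bounded by 1e-12 in the package's own tests).
#'
#' @param n_datasets number of simulated datasets.
#' @param scenario a [sim_scenario()].
#' @param seed master seed.
#' @param mafs optional vector of MAFs cycled across datasets (overrides
#'   the scenario's).
#' @return list with `max_p_discrepancy`, `max_T_rel_discrepancy`,
#'   `n_datasets`.
#' @export
lossless_check <- function(n_datasets = 100, scenario = sim_scenario(),
                           seed = 1, mafs = NULL) {
  seeds <- rep_seeds(seed, n_datasets)
  dp <- dT <- 0
  for (r in seq_len(n_datasets)) {
    sc <- scenario
    sc$seed <- seeds[r]
    if (!is.null(mafs)) sc$maf <- rep_len(mafs[1L + (r - 1L) %% length(mafs)], sc$K)
    sites <- simulate_multisite(sc)
    a <- sumshare(sites, "distributed")
    b <- sumshare(sites, "pooled")
    dp <- max(dp, abs(a$p_raw - b$p_raw))
    dT <- max(dT, abs(a$statistic - b$statistic) / max(1, b$statistic))
  }
  list(max_p_discrepancy = dp, max_T_rel_discrepancy = dT,
       n_datasets = n_datasets)
}

#' Power as a function of sample size, individual vs integrated
#'
#' For each dataset size, estimates the power of the distributed test on
#' that dataset alone; then estimates power when all datasets are
#' integrated in one distributed analysis (total n the sum of sizes).
#'
#' @param sizes vector of per-dataset sample sizes.
#' @param scenario base [sim_scenario()]; its K and n_per_site are replaced.
#' @param reps repetitions.
#' @param alpha significance level.
#' @param seed master seed.
#' @return data frame with one row per individual size plus an
#'   `"integrated"` row; columns analysis, n_total, rejection_rate,
#'   monte_carlo_se.
#' @export
sample_size_study <- function(sizes, scenario = sim_scenario(pattern = "same"),
                              reps = 200, alpha = 0.05, seed = 1) {
  seeds <- rep_seeds(seed, reps)
  K <- length(sizes)
  rej_each <- integer(K)
  rej_int <- 0L
  for (r in seq_len(reps)) {
    sc <- scenario
    sc$K <- K
    sc$n_per_site <- sizes
    sc$maf <- rep_len(scenario$maf, K)
    sc$seed <- seeds[r]
    sites <- simulate_multisite(sc)
    for (k in seq_len(K))
      rej_each[k] <- rej_each[k] + (sumshare(sites[[k]], "pooled")$p_raw < alpha)
    rej_int <- rej_int + (sumshare(sites, "distributed")$p_raw < alpha)
  }
  rate <- c(rej_each, rej_int) / reps
  data.frame(
    analysis = c(paste0("n=", sizes), "integrated"),
    n_total = c(sizes, sum(sizes)),
    rejection_rate = rate,
    monte_carlo_se = sqrt(rate * (1 - rate) / reps),
    stringsAsFactors = FALSE
  )
}
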