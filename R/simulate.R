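#' Simulate Hardy-Weinberg genotypes
#'
#' I.i.d. additive genotypes for one SNP with minor allele frequency `maf`
#' under Hardy-Weinberg equilibrium:
#' \eqn{P(0,1,2) = ((1-p)^2,\, 2p(1-p),\, p^2)}.
#'
#' @param n number of subjects.
#' @param maf minor allele frequency in \[0, 0.5\].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return integer vector of 0/1/2 genotypes.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (is.na(maf) || maf < 0 || maf > 0.5)
    stop("maf must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample(0:2, n, replace = TRUE, prob = probs)
}

#' Effect-size vector for a pleiotropy pattern
#'
#' Expands a reference effect size into the per-phenotype log-odds-ratio
#' vector for the standard simulation patterns:
#' * `"same"` — all q effects equal `beta_ref`;
#' * `"opposite"` — the first \eqn{\lceil q/2 \rceil} phenotypes get
#'   `+beta_ref`, the rest `-beta_ref`;
#' * `"sparse"` — decaying effects \eqn{2^{-i} \beta_{ref}} for
#'   \eqn{i = 1..q} (so the first phenotype gets `beta_ref/2`); with
#'   `sparse_from_one = TRUE` the decay starts at \eqn{2^0}, i.e. the first
#'   phenotype gets the full `beta_ref`;
#' * `"null"` — all zeros.
#'
#' @param pattern one of `"same"`, `"opposite"`, `"sparse"`, `"null"`.
#' @param q number of phenotypes.
#' @param beta_ref reference effect magnitude (log odds ratio).
#' @param sparse_from_one start the sparse decay at \eqn{2^0}.
#' @return numeric vector of length q.
#' @export
beta_pattern <- function(pattern, q, beta_ref,
                         sparse_from_one = FALSE) {
  if (q < 1) stop("q must be at least 1")
  switch(pattern,
    same = rep(beta_ref, q),
    opposite = {
      npos <- ceiling(q / 2)
      c(rep(beta_ref, npos), rep(-beta_ref, q - npos))
    },
    sparse = {
      i <- seq_len(q) - if (sparse_from_one) 1 else 0
      2^(-i) * beta_ref
    },
    null = rep(0, q),
    stop("unknown pattern '", pattern, "'")
  )
}

pheno_linear_predictor <- function(x, beta, beta0, gender, age, gamma, delta) {
  eta <- beta0 + outer(as.numeric(x), as.numeric(beta))
  if (!is.null(gender)) eta <- eta + gender * gamma
  if (!is.null(age)) eta <- eta + age * delta
  eta
}

#' Simulate independent binary phenotypes from the logistic model
#'
#' Each cell is an independent Bernoulli draw with
#' \eqn{P(Y_{ij}=1) = \mathrm{expit}(\beta_0 + x_i \beta_j
#' [+ \mathrm{gender}_i\gamma + \mathrm{age}_i\delta])}.
#'
#' @param x genotype vector (length n).
#' @param beta length-q effect vector (log odds ratios).
#' @param beta0 intercept; the default -0.5 gives ~38% baseline prevalence.
#' @param gender,age optional length-n covariate vectors.
#' @param gamma,delta covariate effects (defaults 0.1 and 0.05).
#' @param seed optional integer seed.
#' @return n x q matrix of 0/1 phenotypes.
#' @export
simulate_phenotypes <- function(x, beta, beta0 = -0.5,
                                gender = NULL, age = NULL,
                                gamma = 0.1, delta = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eta <- pheno_linear_predictor(x, beta, beta0, gender, age, gamma, delta)
  n <- nrow(eta); q <- ncol(eta)
  Y <- matrix(rbinom(n * q, 1, expit(eta)), n, q)
  colnames(Y) <- paste0("y", seq_len(q))
  Y
}

#' Simulate correlated binary phenotypes via a Gaussian copula
#'
#' Draws a latent multivariate normal \eqn{z_i \sim N(0, R)} per subject and
#' sets \eqn{Y_{ij} = 1} iff \eqn{\Phi(z_{ij}) < \mathrm{expit}(\beta_0 +
#' x_i\beta_j)}. Marginally each cell is Bernoulli with exactly the same
#' probability as in [simulate_phenotypes()] — the copula changes only the
#' dependence — and `R = I` reproduces the independent generator in
#' distribution. Realized correlations on the binary scale are attenuated
#' relative to the latent `R`.
#'
#' @param x genotype vector.
#' @param beta length-q effect vector.
#' @param beta0 intercept.
#' @param R q x q latent correlation matrix (symmetric PSD, unit diagonal);
#'   see [block_correlation()] for the two-cluster default design.
#' @param gender,age,gamma,delta optional covariates as in
#'   [simulate_phenotypes()].
#' @param seed optional integer seed.
#' @return n x q matrix of 0/1 phenotypes.
#' @export
simulate_phenotypes_correlated <- function(x, beta, beta0 = -0.5, R,
                                           gender = NULL, age = NULL,
                                           gamma = 0.1, delta = 0.05,
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- as.matrix(R)
  q <- length(beta)
  if (!all(dim(R) == q)) stop("R must be ", q, " x ", q)
  if (max(abs(R - t(R))) > 1e-12 || max(abs(diag(R) - 1)) > 1e-12)
    stop("R must be symmetric with unit diagonal")
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < -1e-10) stop("R is not positive semi-definite")
    ch <- t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q))
  }
  eta <- pheno_linear_predictor(x, beta, beta0, gender, age, gamma, delta)
  n <- nrow(eta)
  Z <- matrix(rnorm(n * q), n, q) %*% ch
  Y <- (pnorm(Z) < expit(eta)) + 0
  colnames(Y) <- paste0("y", seq_len(q))
  Y
}

#' Two-cluster latent correlation matrix
#'
#' Phenotypes split into two equal blocks; within-block latent correlation
#' `rho`, zero between blocks, unit diagonal.
#'
#' @param q number of phenotypes.
#' @param rho within-block correlation (default 0.5).
#' @return q x q correlation matrix.
#' @export
block_correlation <- function(q, rho = 0.5) {
  block <- rep(c(1L, 2L), c(ceiling(q / 2), floor(q / 2)))
  R <- (outer(block, block, `==`)) * rho
  diag(R) <- 1
  R
}

#' Simulate subject covariates
#'
#' Gender is Bernoulli(0.5); age is Normal(mean 65, sd 20); discretized age
#' is 0 for age < 50, 1 for 50 <= age < 75, 2 for age >= 75.
#'
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return data frame with columns `gender`, `age`, `age_discretized`.
#' @export
simulate_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gender <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 65, 20)
  data.frame(gender = gender, age = age,
             age_discretized = discretize_age(age))
}

#' @rdname simulate_covariates
#' @param age numeric age vector.
#' @export
discretize_age <- function(age) {
  ifelse(age < 50, 0L, ifelse(age < 75, 1L, 2L))
}

#' Describe a multi-site simulation scenario
#'
#' Collects the design of one simulated study: K sites, per-site sample
#' sizes and minor allele frequencies, q phenotypes with a pleiotropy
#' pattern and effect magnitude, optional phenotype correlation and optional
#' gender/age covariates. Defaults are the standard desk-scale power design:
#' ten sites of 100 patients, ten phenotypes with ~40% baseline prevalence
#' (intercept -0.5) and a low-frequency SNP (MAF 0.05).
#'
#' @param K number of sites.
#' @param n_per_site per-site sample size (scalar or length-K vector).
#' @param q number of phenotypes.
#' @param maf per-site minor allele frequency (scalar or length-K).
#' @param pattern effect pattern for [beta_pattern()].
#' @param beta_ref effect magnitude.
#' @param beta0 intercept.
#' @param correlation optional q x q latent correlation matrix, or `TRUE`
#'   for the two-cluster [block_correlation()] default.
#' @param covariates simulate gender/age and adjust via strata.
#' @param gamma,delta covariate effects.
#' @param sparse_from_one passed to [beta_pattern()].
#' @param seed integer seed for [simulate_multisite()].
#' @return list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(K = 10, n_per_site = 100, q = 10, maf = 0.05,
                         pattern = "same", beta_ref = 0.3, beta0 = -0.5,
                         correlation = NULL, covariates = FALSE,
                         gamma = 0.1, delta = 0.05,
                         sparse_from_one = FALSE, seed = NULL) {
  n_per_site <- rep_len(n_per_site, K)
  maf <- rep_len(maf, K)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (isTRUE(correlation)) correlation <- block_correlation(q)
  structure(
    list(K = K, n_per_site = n_per_site, q = q, maf = maf,
         pattern = pattern, beta_ref = beta_ref, beta0 = beta0,
         correlation = correlation, covariates = covariates,
         gamma = gamma, delta = delta, sparse_from_one = sparse_from_one,
         seed = seed),
    class = "sim_scenario"
  )
}

#' Simulate a multi-site study
#'
#' Generates K independent site datasets under one scenario: per-site
#' Hardy-Weinberg genotypes at the site's MAF, phenotypes from the logistic
#' model (Gaussian copula when a correlation matrix is given), and — when
#' covariates are on — gender and discretized age crossed into stratum
#' labels. The effect vector is identical across sites (homogeneous
#' effects). Fully reproducible under the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return list of K [site_dataset()] objects.
#' @export
simulate_multisite <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  beta <- beta_pattern(scenario$pattern, scenario$q, scenario$beta_ref,
                       sparse_from_one = scenario$sparse_from_one)
  lapply(seq_len(scenario$K), function(k) {
    n <- scenario$n_per_site[k]
    x <- simulate_genotypes(n, scenario$maf[k])
    if (scenario$covariates) {
      cov <- simulate_covariates(n)
      gender <- cov$gender; age <- cov$age
      strata <- paste0("g", gender, "_a", cov$age_discretized)
    } else {
      gender <- NULL; age <- NULL; strata <- NULL
    }
    Y <- if (is.null(scenario$correlation)) {
      simulate_phenotypes(x, beta, scenario$beta0, gender, age,
                          scenario$gamma, scenario$delta)
    } else {
      simulate_phenotypes_correlated(x, beta, scenario$beta0,
                                     scenario$correlation, gender, age,
                                     scenario$gamma, scenario$delta)
    }
    site_dataset(x, Y, strata = strata, site_id = paste0("site", k))
  })
}
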