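test_that("genotypes follow Hardy-Weinberg proportions", {
  expect_equal(simulate_genotypes(50, 0, seed = 1), rep(0, 50))
  expect_error(simulate_genotypes(10, 0.7), "maf")
  withr::with_seed(31, g <- simulate_genotypes(1e5, 0.3))
  # allele frequency within 0.005 of target
  expect_lt(abs(mean(g) / 2 - 0.3), 0.005)
  # chi-square goodness of fit against ((1-p)^2, 2p(1-p), p^2)
  obs <- tabulate(g + 1L, 3L)
  expected <- c(0.49, 0.42, 0.09)
  gof <- chisq.test(obs, p = expected)
  expect_gt(gof$p.value, 0.001)
  withr::with_seed(32, g5 <- simulate_genotypes(4e4, 0.5))
  expect_equal(as.numeric(table(g5) / 4e4), c(0.25, 0.5, 0.25),
               tolerance = 0.05)
})

test_that("effect patterns expand as specified", {
  expect_equal(beta_pattern("same", 10, 0.3), rep(0.3, 10))
  expect_equal(beta_pattern("opposite", 10, 0.3),
               c(rep(0.3, 5), rep(-0.3, 5)))
  expect_equal(beta_pattern("opposite", 5, 1), c(1, 1, 1, -1, -1))
  expect_equal(beta_pattern("sparse", 3, 1), c(0.5, 0.25, 0.125))
  expect_equal(beta_pattern("sparse", 3, 1, sparse_from_one = TRUE),
               c(1, 0.5, 0.25))
  expect_equal(beta_pattern("null", 4, 9), rep(0, 4))
  expect_error(beta_pattern("zigzag", 3, 1), "unknown pattern")
})

test_that("independent phenotypes have the logistic marginal prevalence", {
  withr::with_seed(33, {
    x <- simulate_genotypes(1e5, 0.05)
    Y0 <- simulate_phenotypes(x, beta = rep(0, 3), beta0 = -0.5)
  })
  # beta = 0: prevalence expit(-0.5) = 0.3775, the ~40% design point
  expect_equal(colMeans(Y0), rep(plogis(-0.5), 3),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_true(all(Y0 %in% 0:1))
  # beta0 -> -Inf limit: all zero
  withr::with_seed(34,
    Yz <- simulate_phenotypes(rbinom(500, 2, 0.3), beta = 0.2, beta0 = -20))
  expect_equal(sum(Yz), 0)
})

test_that("phenotype generator supports parameter recovery", {
  withr::with_seed(35, {
    x <- simulate_genotypes(50000, 0.3)
    Y <- simulate_phenotypes(x, beta = 0.5, beta0 = -0.5)
  })
  fit <- logistic_fit(Y[, 1], x)
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)
})

test_that("copula generator preserves marginals and block correlation", {
  q <- 10
  R <- block_correlation(q, 0.5)
  expect_equal(diag(R), rep(1, q))
  expect_equal(R[1, 2], 0.5)   # within first block
  expect_equal(R[1, 10], 0)    # across blocks
  withr::with_seed(36, {
    x <- simulate_genotypes(1e5, 0.05)
    Yc <- simulate_phenotypes_correlated(x, rep(0, q), -0.5, R)
  })
  expect_equal(colMeans(Yc), rep(plogis(-0.5), q),
               tolerance = 0.01, ignore_attr = TRUE)
  C <- cor(Yc)
  ur <- upper.tri(R)
  within <- C[ur & R == 0.5]
  between <- C[ur & R == 0]
  expect_gt(min(within), 0.1)       # positive realized within-block correlation
  expect_lt(max(abs(between)), 0.02)  # none across blocks
  expect_error(
    simulate_phenotypes_correlated(x, rep(0, 2), -0.5,
                                   matrix(c(1, 2, 2, 1), 2)),
    "positive semi-definite")
})

test_that("identity copula matches the independent generator in distribution", {
  withr::with_seed(37, {
    x <- simulate_genotypes(2e4, 0.3)
    Yi <- simulate_phenotypes(x, beta = c(0.4, -0.4), beta0 = -0.5)
    Yc <- simulate_phenotypes_correlated(x, c(0.4, -0.4), -0.5, diag(2))
  })
  expect_equal(colMeans(Yc), colMeans(Yi), tolerance = 0.02, ignore_attr = TRUE)
  # monotonicity: prevalence increases with genotype when beta > 0
  expect_gt(mean(Yc[x == 2, 1]), mean(Yc[x == 0, 1]))
})

test_that("covariates match their generating distributions", {
  expect_equal(discretize_age(c(49.99, 50, 74.99, 75)), c(0L, 1L, 1L, 2L))
  withr::with_seed(38, cov <- simulate_covariates(1e5))
  expect_lt(abs(mean(cov$gender) - 0.5), 0.01)
  expect_equal(mean(cov$age), 65, tolerance = 0.5)
  expect_equal(sd(cov$age), 20, tolerance = 0.5)
  # P(age < 50) = Phi((50 - 65) / 20) = 0.2266
  expect_equal(mean(cov$age_discretized == 0), pnorm(-0.75), tolerance = 0.01)
})

test_that("multi-site simulation honours the scenario and is reproducible", {
  sc <- sim_scenario(K = 10, n_per_site = 100, q = 10, maf = 0.05, seed = 99)
  sites <- simulate_multisite(sc)
  expect_length(sites, 10)
  expect_equal(sum(vapply(sites, `[[`, 0L, "n")), 1000)
  again <- simulate_multisite(sc)
  expect_identical(lapply(sites, `[[`, "genotype"),
                   lapply(again, `[[`, "genotype"))
  expect_identical(lapply(sites, `[[`, "phenotypes"),
                   lapply(again, `[[`, "phenotypes"))

  het <- sim_scenario(K = 3, n_per_site = 2000, maf = c(0.05, 0.1, 0.4),
                      pattern = "same", beta_ref = 0.1, seed = 7)
  hs <- simulate_multisite(het)
  freqs <- vapply(hs, function(s) mean(s$genotype) / 2, 0)
  expect_equal(freqs, c(0.05, 0.1, 0.4), tolerance = 0.25)

  cov_sc <- sim_scenario(K = 2, n_per_site = 50, q = 2, covariates = TRUE,
                         seed = 5)
  cs <- simulate_multisite(cov_sc)
  expect_true(all(grepl("^g[01]_a[012]$", cs[[1]]$strata)))
})
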