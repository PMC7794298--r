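test_that("score statistic is the quadratic form S V^-1 S'", {
  expect_equal(score_statistic(1, matrix(0.5))$statistic, 2)
  expect_equal(score_statistic(c(0, 0), diag(2))$statistic, 0)
  expect_error(score_statistic(c(1, 1), matrix(0, 2, 2)), "singular")
  expect_error(score_statistic(c(1, 1), matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("pseudo-inverse mode tests on the non-degenerate subspace", {
  # rank-1 V: score along the live direction only
  V <- matrix(c(1, 1, 1, 1), 2)
  S <- c(1, 1)
  expect_error(score_statistic(S, V), "collinear")
  st <- score_statistic(S, V, pseudo_inverse = TRUE)
  expect_true(st$rank_deficient)
  expect_equal(st$df, 1)
  # Moore-Penrose oracle: V+ = qq'/2 with q = (1,1)/sqrt(2), so S V+ S' = 1
  expect_equal(st$statistic, 1)
  expect_equal(st$statistic,
               drop(t(S) %*% MASS::ginv(V) %*% S), tolerance = 1e-12)
})

test_that("p-values follow the chi-squared reference with a reporting floor", {
  expect_equal(pvalue_from_statistic(0, 1)$p_value, 1)
  # frozen from the chi-squared survival oracle: P(chi2_1 > 2) = 0.1572992
  expect_equal(pvalue_from_statistic(2, 1)$p_value, 0.1572992, tolerance = 1e-6)
  big <- pvalue_from_statistic(1000, 5)
  expect_true(big$p_floored)
  expect_equal(big$p_value, 2.22e-16)
  expect_lt(big$p_raw, 2.22e-16)
  expect_error(pvalue_from_statistic(-1, 1), "nonnegative")
  expect_error(pvalue_from_statistic(1, 0), "degrees of freedom")
})

test_that("worked dataset gives T = 2, p = 0.1573 on both code paths", {
  d <- worked_dataset()
  for (m in c("distributed", "pooled")) {
    fit <- sumshare(d, m)
    expect_equal(fit$statistic, 2)
    expect_equal(fit$df, 1)
    expect_equal(fit$p_value, 0.1572992, tolerance = 1e-6)
  }
})

test_that("distributed equals pooled on random multi-site data (lossless)", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      sc <- sim_scenario(K = sample(2:5, 1), n_per_site = sample(30:80, 1),
                         q = 3, maf = 0.3,
                         pattern = sample(c("same", "null"), 1),
                         beta_ref = 0.4, seed = sample.int(1e6, 1))
      sites <- simulate_multisite(sc)
      a <- sumshare(sites, "distributed")
      b <- sumshare(sites, "pooled")
      expect_lt(abs(a$p_raw - b$p_raw), 1e-12)
      expect_lt(abs(a$statistic - b$statistic) / max(1, b$statistic), 1e-12)
    }
  })
})

test_that("T is invariant to how rows are partitioned into sites", {
  withr::with_seed(5, d <- random_dataset(120, 3))
  t1 <- sumshare(d)$statistic
  t2 <- sumshare(split_sites(d, 2))$statistic
  t10 <- sumshare(split_sites(d, 10))$statistic
  expect_lt(abs(t2 - t1) / max(1, t1), 1e-12)
  expect_lt(abs(t10 - t1) / max(1, t1), 1e-12)
})

test_that("T is invariant to affine genotype recoding and phenotype order", {
  withr::with_seed(6, d <- random_dataset(80, 3))
  base <- sumshare(d)
  # affine map a*x + b with x in {0,1,2} staying in {0,1,2}: flip 2 - x
  flip <- site_dataset(2 - d$genotype, d$phenotypes, site_id = "flip")
  expect_equal(sumshare(flip)$statistic, base$statistic, tolerance = 1e-12)
  perm <- site_dataset(d$genotype, d$phenotypes[, c(3, 1, 2)], site_id = "perm")
  expect_equal(sumshare(perm)$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(sumshare(perm)$p_raw, base$p_raw, tolerance = 1e-12)
})

test_that("duplicated phenotype columns make V singular", {
  withr::with_seed(7, d <- random_dataset(50, 1))
  dup <- site_dataset(d$genotype,
                      cbind(a = d$phenotypes[, 1], b = d$phenotypes[, 1]))
  expect_error(sumshare(dup), "singular")
  st <- sumshare(dup, pseudo_inverse = TRUE)
  expect_true(st$rank_deficient)
  expect_equal(st$df, 1)
})

test_that("V is symmetric PSD across random inputs", {
  withr::with_seed(8, {
    for (rep in 1:10) {
      d <- random_dataset(40, 4)
      fit <- sumshare(d)
      expect_equal(fit$V, t(fit$V))
      ev <- eigen(fit$V, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10 * max(abs(ev)))
    }
  })
})

test_that("stratified adjustment centers within covariate cells", {
  # two strata with very different prevalences and genotype means:
  # the adjusted test must use cell-level references, not global ones
  withr::with_seed(13, {
    n <- 200
    stratum <- rep(c("young", "old"), each = n / 2)
    x <- c(simulate_genotypes(n / 2, 0.1), simulate_genotypes(n / 2, 0.4))
    p <- ifelse(stratum == "young", 0.2, 0.7)
    Y <- cbind(y = rbinom(n, 1, p))
  })
  d <- site_dataset(x, Y, strata = stratum)
  fit <- sumshare(d)
  # oracle: stratum-centered score computed directly
  u <- (x - ave(x, stratum)) * (Y[, 1] - ave(Y[, 1], stratum))
  expect_equal(unname(fit$S), sum(u), tolerance = 1e-12)
  expect_equal(unname(fit$V[1, 1]), sum(u^2), tolerance = 1e-12)
  # and the adjusted distributed path is still lossless
  parts <- split_sites(d, 4)
  expect_lt(abs(sumshare(parts)$p_raw - fit$p_raw), 1e-12)
})

test_that("summary and print expose per-phenotype diagnostics", {
  withr::with_seed(14, d <- random_dataset(60, 3))
  fit <- sumshare(d)
  s <- summary(fit)
  expect_s3_class(s, "summary.sumshare")
  expect_equal(nrow(s$per_phenotype), 3)
  expect_equal(s$per_phenotype$z,
               unname(fit$S / sqrt(diag(fit$V))))
  expect_output(print(fit), "Pleiotropy score test")
  expect_output(print(s), "Per-phenotype")
})
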