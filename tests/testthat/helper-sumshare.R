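# shared fixtures and independent oracles

# four-subject worked dataset: x-bar = 1, y-bar = 0.5,
# S = sum x(y - ybar) = 1, V = sum (x - xbar)^2 (y - ybar)^2 = 0.5, T = 2
worked_dataset <- function() {
  site_dataset(c(0, 1, 2, 1), cbind(y = c(0, 1, 1, 0)), site_id = "worked")
}

# independent oracle: score test evaluated directly on combined rows with
# the uncentered score sum x_i (y_i - ybar); no package plumbing involved
oracle_score_test <- function(x, Y) {
  Y <- as.matrix(Y)
  ybar <- colMeans(Y)
  xbar <- mean(x)
  C <- sweep(Y, 2, ybar)
  S <- colSums(x * C)
  V <- t(C) %*% (C * (x - xbar)^2)
  T <- drop(t(S) %*% solve(V) %*% S)
  list(S = S, V = V, statistic = T,
       p = pchisq(T, df = ncol(Y), lower.tail = FALSE))
}

# small random multi-phenotype dataset with non-degenerate columns
random_dataset <- function(n = 60, q = 3, maf = 0.3, site_id = "r") {
  repeat {
    x <- simulate_genotypes(n, maf)
    Y <- matrix(rbinom(n * q, 1, 0.4), n, q,
                dimnames = list(NULL, paste0("y", seq_len(q))))
    if (length(unique(x)) > 1L && all(apply(Y, 2, sd) > 0)) break
  }
  site_dataset(x, Y, site_id = site_id)
}

# split one dataset's rows into K sites (deterministic contiguous blocks)
split_sites <- function(data, K) {
  idx <- split(seq_len(data$n), rep(seq_len(K), length.out = data$n))
  lapply(seq_len(K), function(k) {
    i <- idx[[k]]
    site_dataset(data$genotype[i], data$phenotypes[i, , drop = FALSE],
                 strata = data$strata[i, , drop = FALSE],
                 site_id = paste0("part", k))
  })
}

# 1000 distributed-test results under the null scenario (10 sites x 100,
# q = 10, beta = 0, MAF 0.05), computed once and shared by the calibration
# checks; seeded so the suite is reproducible
.null_cache <- new.env(parent = emptyenv())
null_statistics <- function(reps = 1000, seed = 20260928) {
  key <- paste0("s", seed, "_", reps)
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  sc <- sim_scenario(K = 10, n_per_site = 100, q = 10, maf = 0.05,
                     pattern = "null", beta0 = -0.5)
  seeds <- withr::with_seed(seed, sample.int(2147483646L, reps))
  T_ <- p_ <- numeric(reps)
  for (r in seq_len(reps)) {
    sc$seed <- seeds[r]
    fit <- sumshare(simulate_multisite(sc), "distributed")
    T_[r] <- fit$statistic
    p_[r] <- fit$p_raw
  }
  .null_cache[[key]] <- list(T = T_, p = p_)
  .null_cache[[key]]
}
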