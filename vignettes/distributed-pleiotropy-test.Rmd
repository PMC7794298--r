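---
title: "A lossless distributed score test for pleiotropy: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lossless distributed score test for pleiotropy: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumshare)
```

## The problem

A single genetic variant can influence several diseases at once (pleiotropy).
Detecting this jointly across q binary phenotypes is more powerful than testing
each phenotype separately, but the patients carrying those phenotypes are
typically spread over several health systems whose records cannot be pooled.
This package implements a score test for the joint null hypothesis "the SNP is
associated with none of the q phenotypes" that can be computed *exactly* from
two rounds of summary statistics exchanged between K sites and a central
analyst — the distributed result is mathematically identical to running the
test on the pooled patient-level rows, not an approximation to it.

## Model and statistic

For phenotype $j$ we posit a marginal logistic model
$\operatorname{logit} \Pr(Y_j = 1 \mid X) = \alpha_j + \beta_j X$ with $X \in
\{0,1,2\}$ the additive allele count. The q marginal log-likelihoods are summed
into a composite log-likelihood — dependence between phenotypes is deliberately
left unmodelled, and inference is protected by a robust (empirical) variance.
The score test of $H_0 : \beta = 0$ profiles out the intercepts, which under
the null are just the pooled phenotype prevalences $\bar y_j$. With
$\bar x$ the pooled genotype mean, each subject contributes the score vector

$$u_i = (x_i - \bar x)\,(y_i - \bar y), \qquad
S = \sum_i u_i, \qquad V = \sum_i u_i u_i^\top,$$

and the statistic is $T = S V^{-1} S^\top$, asymptotically $\chi^2_q$ under
$H_0$, with $p = 1 - \Psi_q(T)$. Note that $V$ is the *uncentered* second
moment of the per-subject scores; since $E(u_i) = 0$ under the null this is a
consistent variance estimate, and it is the form that decomposes over sites.

Two equivalent forms of $S$ exist: the uncentered $\sum_i x_i (y_i - \bar y)$
and the centered $\sum_i (x_i - \bar x)(y_i - \bar y)$. They differ by
$\bar x \sum_i (y_i - \bar y)$, which is exactly zero over the pooled data, so
$T$ is identical either way. The package computes the centered form throughout
because it is the one that generalizes to covariate strata (below) and makes
the unadjusted analysis a literal special case of the adjusted one.

### The two-round protocol

1. **Round 1** — each site $k$ shares, per phenotype and covariate stratum,
   its subject count, phenotype sum and genotype sum
   (`site_stage1()`). Unadjusted, that is just $n_k, n_k\bar y_k, n_k\bar x_k$.
2. **Pooling** — the analyst forms pooled means
   $\bar y = \sum_k n_k \bar y_k / n$, $\bar x = \sum_k n_k \bar x_k / n$
   (per stratum when adjusting) and returns them (`pool_stage1()`).
3. **Round 2** — each site computes $S_k = \sum_{i \in k} u_i$ and
   $V_k = \sum_{i \in k} u_i u_i^\top$ against the *pooled* means
   (`site_stage2()`).
4. **Test** — the analyst sums $S = \sum_k S_k$, $V = \sum_k V_k$ and forms
   $T$ and $p$ (`pool_stage2()`, `score_statistic()`,
   `pvalue_from_statistic()`).

Because every pooled quantity is a sum of site-level sums, the protocol is
lossless by construction; the only discrepancy between `sumshare(sites,
"distributed")` and `sumshare(sites, "pooled")` is floating-point summation
order, bounded in the package's tests at $10^{-12}$. Only counts, sums and
q×q matrices ever leave a site — no patient-level rows.

```{r example}
sites <- simulate_multisite(sim_scenario(K = 3, n_per_site = 200, q = 4,
                                         maf = 0.3, pattern = "same",
                                         beta_ref = 0.4, seed = 42))
dist <- sumshare(sites, method = "distributed")
pooled <- sumshare(sites, method = "pooled")
dist
abs(dist$p_raw - pooled$p_raw)
```

## Covariate adjustment by stratification

The test can adjust for *categorical* covariates (e.g. gender × an age bin)
by centering within covariate cells: subject $i$'s component for phenotype
$j$ becomes $(x_i - \bar x_{j,s})\,(y_{ij} - p_{j,s})$ where $s$ is the
subject's stratum for that phenotype, and $p_{j,s}$, $\bar x_{j,s}$ are
*pooled* within-stratum means. The null fitted values are then stratum
prevalences, which is precisely the profiled null of a logistic model with a
separate intercept per cell. Strata may differ between phenotypes (a
different age at diagnosis per disease); they are opaque labels, crossed by
the caller or by `read_site_table()`. Because stratum means pool from
per-stratum counts and sums, adjustment preserves losslessness. Continuous
covariates cannot be adjusted this way — discretize them (see
`discretize_age()` for the 50/75-year convention) or use a different method;
this is an inherent trade-off of the lossless design.

With a single stratum the adjusted computation *is* the unadjusted one — the
same code path, hence bit-for-bit identical results.

## Degenerate inputs and numerical choices

* **Singular $V$** (monomorphic SNP, constant phenotype, duplicated
  phenotypes): a hard error naming the degeneracy. `pseudo_inverse = TRUE`
  opts into a Moore–Penrose inverse with `df = rank(V)` and a
  `rank_deficient` flag; this is opt-in because silently changing the
  degrees of freedom changes the null reference. Rank is called at a
  relative eigenvalue tolerance of 1e-10.
* **P-value floor**: p-values below 2.22e-16 are reported at that floor with
  a `p_floored` flag; the raw value is kept in `p_raw` and floor application
  never affects internal comparisons.
* **Missing phenotypes**: complete-case at read time by default;
  `impute_phenotypes()` offers a seeded Bernoulli draw from the observed
  prevalence (stays binary) or a deterministic expected-value fill
  (fractional, accepted by the score formulas, which only need
  $y \in [0,1]$).
* **Lossless tolerance**: distributed-vs-pooled assertions use 1e-12
  (relative for $T$), generous against summation-order effects.
* **Summary JSON**: numbers serialize with 17 significant digits, the
  minimum that round-trips IEEE doubles bit-exactly.

## The synthetic-data generator

`simulate_multisite()` reproduces the evaluation designs used throughout:

* **Genotypes**: i.i.d. Hardy–Weinberg draws,
  $P(0,1,2) = ((1-p)^2, 2p(1-p), p^2)$, with per-site MAF (heterogeneous
  MAFs across sites are supported, e.g. 0.05/0.1/0.4).
* **Phenotypes**: independent Bernoulli cells with
  $P(Y_{ij}=1) = \operatorname{expit}(\beta_0 + x_i\beta_j)$. The default
  intercept $\beta_0 = -0.5$ gives baseline prevalence
  $\operatorname{expit}(-0.5) \approx 0.378$, the "roughly 40%" design
  point.
* **Effect patterns** (`beta_pattern()`): `same` (all $+\beta$), `opposite`
  (first half $+\beta$, second half $-\beta$), `sparse` (decaying
  $2^{-i}\beta$ — read literally, so phenotype 1 gets $\beta/2$; a
  `sparse_from_one` switch starts the decay at $2^0$ since the printed decay
  rule is self-referential), `null`.
* **Correlated phenotypes**: a Gaussian copula — latent
  $z_i \sim N(0, R)$, $Y_{ij} = 1$ iff $\Phi(z_{ij}) <$ the logistic
  probability. This preserves the logistic marginals *exactly* for any $R$
  (the tests verify prevalence to ±0.01 at $n = 10^5$), degenerates to the
  independent generator at $R = I$, and realizes attenuated correlations on
  the binary scale (latent 0.5 → binary ≈ 0.33 at these prevalences). The
  default $R$ has two equal blocks with within-block latent correlation 0.5,
  the two-cluster design; the generating source is described only as
  multivariate-normal-based, so the copula is this package's concrete
  choice, documented rather than assumed.
* **Covariates**: gender ~ Bernoulli(0.5), age ~ N(65, 20²), age binned at
  50 and 75; effects $\gamma = 0.1$, $\delta = 0.05$ (the age effect chosen
  of the order of the average genetic effect).

What the generator does *not* emulate: linkage disequilibrium and population
structure, relatedness, phenotype misclassification, site-specific
case-mix differences, and dosage uncertainty. Passing tests therefore
establish the statistical machinery on clean Bernoulli/HWE data, not
robustness to real-EHR artefacts.

## Monte-Carlo harness and problem sizes

`estimate_power()`, `compare_methods()` (paired: all methods see identical
data within a repetition), `lossless_check()` and `sample_size_study()` wrap
the generator and the tests. Per-repetition seeds derive deterministically
from one master seed, so the distributed and pooled arms consume identical
data and their rejection counts can be compared exactly.

The package's own test suite runs calibration at 1000 repetitions of the
10-sites × 100-subjects × 10-phenotypes design and power comparisons at 200
paired repetitions per panel; the desk-scale defaults (`reps = 200`) keep a
full harness run in minutes on one CPU while leaving `reps = 1000`
available.

## Calibration and power: what to expect

Two behaviours of the statistic at the default study scale are worth knowing
about, both verified by the suite's Monte-Carlo checks and both properties
of the method rather than of this implementation:

* **Mild conservatism at small effective sample sizes.** $V$ is the
  uncentered second moment $\sum u_i u_i^\top$; self-normalizing by it
  shrinks $T$ relative to using the centered covariance (the two are related
  by $T = T_c/(1 + T_c/n)$ in one dimension). At MAF 0.05 with n = 1000 and
  q = 10 the empirical type-I error sits slightly below the nominal 5%
  (around 4% over thousands of null replicates) and converges to 5% as n
  grows (5.0% at n = 10,000 in the package's diagnostics). The q = 10
  chi-square reference is otherwise accurate (Kolmogorov–Smirnov at 1000
  replicates).
* **The joint test is not uniformly more powerful than min-p PheWAS.** With
  many same-direction effects it clearly dominates (e.g. 0.80 vs 0.61 at
  $\beta = 0.3$, and 0.84 vs 0.52 under opposite directions, 200 paired
  repetitions). But a Bonferroni minimum-p over per-phenotype logistic fits
  is near-optimal when one phenotype carries most of the signal — under the
  decaying sparse pattern it edges out the q-df joint test — and positive
  within-block correlation inflates the variance of the score component
  aligned with a same-direction effect vector, which the joint statistic
  correctly pays for while marginal PheWAS fits do not. Users with strong
  prior sparsity should expect min-p PheWAS to be competitive; the joint
  test's advantage is broad, not universal, and shrinks with phenotype
  correlation at these block strengths.

## Design choices that were genuinely open

* **Adjusted-score form**: the stratified centering above was chosen because
  it (a) reduces exactly to the unadjusted statistic with one stratum,
  (b) keeps the protocol lossless, and (c) supports phenotype-specific
  strata. Whether the genotype should be centered by the pooled mean or per
  stratum in $V$ was open; per-stratum centering was adopted for coherence
  with the null model (cell-wise fitted values).
* **PheWAS decision order**: fit per site → inverse-variance-weight per
  phenotype → Bonferroni min-p. Wald p-values (not LRT) are used, as that is
  what inverse-variance weighting consumes.
* **Separation in site-level fits** is flagged and the fit excluded from the
  meta-analysis rather than aborting — small sites with rare SNPs separate
  routinely.
* **Minor-allele definition** in VCF extraction follows the pooled data with
  ties toward ALT; coordinates are 1-based per VCF convention.

## Limitations

Continuous covariates cannot be adjusted without discretization. The
composite-likelihood score test gives a single joint p-value, not
per-phenotype effect estimates under the alternative. The conservatism noted
above means borderline signals at rare MAF and small n are slightly
under-rejected. Heterogeneous per-site effects violate the homogeneity
assumption built into the pooled score; the test then targets an averaged
alternative.
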