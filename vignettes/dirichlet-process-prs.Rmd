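---
title: "Polygenic scores with a Dirichlet-process effect-size prior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores with a Dirichlet-process effect-size prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dprs)
```

## The problem

A genome-wide association study (GWAS) reports, for each SNP $i$, a marginal
regression coefficient $\hat\beta_i$, a sample size $N_i$ and a p-value.
Building a polygenic risk score (PRS) means converting these *marginal*
estimates — which are confounded by linkage disequilibrium (LD) among nearby
SNPs — into *joint* effect estimates that can be summed over an individual's
genotype.  With standardized genotypes $X$ and phenotype $y$, the underlying
model is $y = X\beta + \epsilon$, and the marginal estimates satisfy
approximately

$$\hat\beta \mid \beta \sim N(R\beta,\; R/N),$$

where $R$ is the LD correlation matrix, estimable from an external reference
panel.  `dprs` performs full Bayesian inference for $\beta$ under this
likelihood (and two robustified variants), with a nonparametric prior on the
effect-size distribution, and returns posterior-mean effects ready for
scoring.

## The prior

Parametric PRS methods commit to a specific effect-size distribution —
a single normal, a point-normal, or a small normal mixture.  Real traits
vary widely in architecture, so `dprs` instead places a Dirichlet-process
(DP) prior on the per-SNP effect variance, which by stick-breaking is an
infinite normal mixture

$$\beta_i \sim \sum_{k} p_k\,N(0,\sigma^2_k), \qquad
p_k = V_k \prod_{m<k}(1-V_m), \qquad V_k \sim \mathrm{Beta}(1,\alpha),$$

truncated at $K$ components ($K = 1000$ by default; the number of occupied
components in practice is far smaller, so the truncation is inert).  Two
refinements matter:

* **Exact point mass at zero.**  Component 0 is pinned at $\sigma^2_0 = 0$,
  implemented as exact zeros rather than a tiny variance, giving Bayesian
  variable selection for free.
* **Square-of-uniform base distribution.**  Component standard deviations
  are drawn uniformly on $(0, u)$; this avoids the hidden informativeness of
  inverse-gamma bases near zero.  The bound is `u = 1` on the
  standard-deviation scale: standardized per-SNP effects are far below 1 for
  any polygenic trait, so the truncation is effectively uninformative while
  keeping every conditional proper.
* **Parameter expansion.**  The model is overparametrized as
  $\beta_i = \eta\,\gamma_i$ with $\eta \sim N(0,1)$.  Only $\beta$ is
  identified or reported; the expansion improves mixing of the Gibbs
  sampler by letting a single global draw rescale all effects.

The concentration parameter $\alpha$ controls how many components carry
weight and gets a weakly informative Gamma(0.1, 0.1) hyperprior; both it and
the $\eta$ prior variance are configuration-exposed in `dp_prior()`.

## Three likelihoods

`likelihood_spec()` selects how $\hat\beta$ relates to $\beta$:

* **plain** — the exact model above.  Appropriate when the reference panel
  individuals are the GWAS individuals (as in our simulations).
* **overlap** — when SNPs were genotyped on partially overlapping cohorts
  (e.g. two arrays), the covariance is $R \circ H$ with
  $H_{ii} = 1/N_i$, $H_{ij} = N_{s,ij}/(N_i N_j)$, where $N_{s,ij}$ counts
  shared individuals.  Requires per-SNP cohort labels and a shared-count
  rule.
* **regularized** (default) — overlap counts are rarely published, and
  meta-analyzed summary statistics carry extra heterogeneity (including
  deflation from double genomic control, undone by dividing the input by a
  constant $c$).  The covariance is taken as $(R + aN\,I)/N$, which shrinks
  the implied cross-SNP correlation of marginal effects to
  $R_{ij}/(1 + aN)$.  The default $aN = 0.1$ follows common practice for
  real traits; the mismatch experiments below use $aN = 0.25$.

Whatever the mode, the likelihood enters the sampler only through per-block
quadratic summaries $(B_b, v_b, \tilde N_b)$ with
$\log L(\beta) = \tilde N(\beta^\top v - \tfrac12 \beta^\top B \beta) + c$;
`build_block_quadratics()` performs the mode-specific linear algebra once,
up front.  $\tilde N_b$ is the median per-SNP sample size in the block —
per-SNP sizes vary in real data, the likelihood needs one scalar, and the
median is robust to outliers (per-SNP sizes still drive the QC filter).
Kernel inverses use Cholesky factorization with a single automatic
$10^{-6}$ ridge retry (shrinkage should already guarantee positive
definiteness; the retry guards round-off after serialization).

## LD reference and block partition

LD blocks make the Gibbs sampler block-parallel and bound the cost of the
per-block linear algebra.  `partition_blocks()` is a single left-to-right
scan that places a boundary after SNP $i$ exactly when no SNP pair within
the scan window straddles the boundary with $r^2 > 0.1$ — so by
construction no SNP has non-ignorable correlation outside its own block,
which is precisely the independence the block likelihood assumes.
`validate_partition()` re-checks any partition and returns the violating
pairs; a certified partition returns none.  If a block would exceed
`max_block_size` (default 1024, bounding the $O(m^3)$ per-block cost), a
forced cut is placed at the position minimizing the maximum straddling
$r^2$ and the violation is logged rather than hidden.

Sample correlation matrices from a finite panel are noisy and can be
rank-deficient, so each block is shrunk linearly toward the identity:
$(1-\lambda) R_b + \lambda I$.  The `"auto"` intensity is the
variance-minimizing linear shrinkage estimate
$\sum \widehat{\mathrm{Var}}(r_{ij}) / \sum r_{ij}^2$ with
$\widehat{\mathrm{Var}}(r_{ij}) \approx (1-r_{ij}^2)^2/(n_{\mathrm{ref}}-1)$,
clipped to $[0.05, 1]$ for panels of at most 1000 individuals and
$[0.01, 1]$ otherwise; any $\lambda > 0$ guarantees
$\mathrm{eigmin} \ge \lambda$.  (The estimator cited in the LD-shrinkage
literature differs in detail; linear shrinkage keeps the two properties the
sampler needs — positive definiteness and noise damping — and is fully
self-contained.  A fixed intensity can be supplied instead.)

The scan window defaults to 256 SNPs or 1 Mb, whichever is wider — the
scale at which LD is non-ignorable in European-ancestry panels.

## The Gibbs sampler

One sweep updates, in a fixed order: per-block component assignments and
effects (the component is drawn with $\gamma_i$ integrated out, then
$\gamma_i$ from its conjugate normal), cluster variances (inverse-gamma
kernel truncated to $(0, u^2]$, sampled by inverse CDF; the singleton
cluster case has gamma shape zero, where the inverse-CDF route is undefined,
and uses an exact log-scale rejection sampler instead), stick proportions,
$\alpha$, and $\eta$.  Any valid scan order leaves the stationary
distribution unchanged; fixing one is purely a reproducibility decision,
as is the ascending-position SNP order within blocks.

Runs start at the null model (every SNP in component 0), which pairs
naturally with the divergence guard: if $\max_i |\beta_i|$ ever exceeds
$10^3$ — on the standardized scale, absurd — the run aborts and recommends
the regularized likelihood, since blow-ups of this kind are the signature
of summary statistics inconsistent with the LD reference.  A warm start
from marginal effects is available through `mcmc_control(init = )`.

Reproducibility contract: the master seed spawns one RNG substream per LD
block plus one global substream (splitmix64-derived mt19937 states; all
draws are inverse-CDF transforms of 53-bit uniforms).  Block updates are
executed in a thread-count-invariant order, so `n_threads` cannot change
any result — equal seeds give byte-identical outputs.  Defaults are 1000
sweeps with 200 burn-in; the sampler reaches its stationary behavior within
tens of sweeps on the problem sizes below, and the conjugate- and
enumeration-oracle tests bound the residual Monte-Carlo error directly.

## What the simulator emulates — and what it does not

`simulate_panel()` draws continuous Gaussian genotypes with exact
block-diagonal correlation (AR-like decay $\rho^{|i-j|}$ or exchangeable),
optionally discretized to 0/1/2 dosages by Hardy–Weinberg quantile
thresholding.  Continuous genotypes are the default deliberately: the
method consumes only $\hat\beta$ and $R$, so the Gaussian shortcut tests
exactly the assumptions the likelihood makes, at a fraction of the cost.
`simulate_effects()` covers spike-and-slab sparsity (causal fraction
$\pi \in \{10^{-4}, 10^{-3}, 10^{-2}\}$ in the named scenarios, or exact
causal counts), a three-normal mixture with variance multipliers
$(1, 0.1, 0.01)$ and proportions $(10^{-4}, 10^{-4}, 10^{-2})$ whose common
variance is solved so the expected heritability is exactly $h^2$, and an
infinitesimal scenario; in every case $E[\sum\beta_i^2] = h^2$.
`simulate_phenotype()` fixes the *realized* genetic-variance fraction at
$h^2$ to machine precision by rescaling the genetic component and
orthogonalizing the noise against it (mirroring fixed-heritability
simulation tools; a purely theoretical convention is also available).
`marginal_gwas()` computes per-SNP marginal effects, optionally restricting
each SNP to its own cohort of individuals and optionally *misreporting* a
nominal sample size — together these reproduce, by replication, both the
full-overlap covariance $R/N$ and the Hadamard-kernel covariance of
partially overlapping cohorts, which is the simulator's core fidelity
property and is asserted in the test suite.  `direct_sumstats()` skips
individual-level data entirely and samples
$\hat\beta_b \sim N(R_b\beta_b, R_b/N)$ per block.

What passing these tests does *not* show: real LD is neither AR nor block
exchangeable and has no clean zero boundaries; real effect sizes correlate
with allele frequency and annotation; case-control ascertainment,
imputation error and cross-cohort heterogeneity are all absent.  The tests
certify the inference machinery under its own assumptions, not the
method's real-data accuracy.

## Problem sizes and numerical choices

The package's statistical checks run at desk scale, chosen to keep the
whole suite reproducible on a laptop while leaving the assertions sharp:
$M = 2000$ SNPs in 50 AR(0.5) blocks, GWAS size $N = 20000$, $h^2 = 0.5$,
validation cohorts of 5000.  At these sizes the sparse-architecture signal
per causal SNP (20 causals) is strong, and the infinitesimal per-SNP
signal $Nh^2/M = 5$ is moderate — both regimes are informative.  The
mismatch experiment computes half the SNPs' marginal effects on an 80%
subsample of a 10000-individual cohort while reporting the full size, so
the cross-cohort correlation of marginal effects is 80-90% of what the
reference panel implies.  Exact-oracle checks use
50 independent SNPs (conjugate closed form) and a 5-SNP block with $2^5$
enumerated assignment patterns.

Other numerical decisions: assignment log-weights are normalized by
max-subtraction before exponentiation; `log(1 - V)` is floored at $-30$ in
the $\alpha$ update to guard degenerate sticks; cluster-variance draws at
the truncation boundary fall back to $u^2$ when the conditional tail mass
underflows ($< 10^{-14}$); monomorphic panel columns standardize to zero
rather than NaN; nearest-rank (type-1) percentiles define the sample-size
QC threshold (the convention only matters at ties).

## Known limitations

* Effects are reported on the standardized scale after division by $c$;
  per-allele output requires multiplying back by
  $c/\sqrt{2f(1-f)}$ downstream.
* Heritability appears only as the per-iteration diagnostic trace
  $\beta^\top R \beta$; the package does not provide formal heritability
  estimates, posterior inclusion probabilities for fine-mapping,
  annotation-stratified priors, or multi-population likelihoods.
* $aN$ and $c$ are user inputs, not estimated from data.
* The sampler is serial; parallelism is intended at the chromosome level
  (the `fit` subcommand takes a chromosome filter), and the per-block RNG
  substreams mean a future threaded implementation cannot change results.

## A worked miniature

```{r example}
blocks <- replicate(10, outer(1:20, 1:20, function(i, j) 0.5^abs(i - j)),
                    simplify = FALSE)
beta <- simulate_effects(scenario_config("custom", M = 200, h2 = 0.3,
                                         n_causal = 4, seed = 7))
ss <- direct_sumstats(blocks, beta, N = 20000, seed = 8)
ldref <- ld_reference_from_blocks(blocks, ss[, c("snp", "chr", "pos",
                                                 "a1", "a2")])
fit <- dp_fit(ss, ldref, likelihood_spec("plain"), dp_prior(K = 100),
              mcmc_control(n_iter = 400, burn_in = 100, seed = 9))
glance(fit)
cor(tidy(fit)$effect, beta)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(fit)
```
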