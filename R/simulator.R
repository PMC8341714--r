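#' Simulate a genotype panel with block-diagonal LD
#'
#' Generates standardized genotypes whose true correlation is block
#' diagonal: within a block, either AR-like decay `rho^|i - j|` or
#' exchangeable correlation `rho`; zero correlation across blocks.  The
#' default continuous Gaussian genotypes match the model's assumptions
#' exactly (the method consumes only marginal effects and a correlation
#' matrix); optional discretization to 0/1/2 dosages via Hardy-Weinberg
#' quantile thresholding adds genotype-like granularity.
#'
#' @param n Number of individuals.
#' @param block_sizes Integer vector of SNPs per block.
#' @param rho Within-block correlation parameter in `[0, 1)`.
#' @param model `"ar1"` (default) or `"exchangeable"`.
#' @param discretize Threshold to 0/1/2 dosages and re-standardize.
#' @param maf_range Allele-frequency range for discretization.
#' @param chr Chromosome label for the metadata.
#' @param pos_spacing Base-pair spacing between adjacent SNPs.
#' @param seed Optional seed (R RNG).
#' @return A `geno_panel` whose `true_blocks` element holds the list of
#'   true within-block correlation matrices.
#' @export
simulate_panel <- function(n, block_sizes, rho = 0.5,
                           model = c("ar1", "exchangeable"),
                           discretize = FALSE, maf_range = c(0.05, 0.5),
                           chr = 1L, pos_spacing = 1000L, seed = NULL) {
  model <- match.arg(model)
  if (rho < 0 || rho >= 1) abort("rho must be in [0, 1)",
                                 class = "dprs_config_error")
  if (!is.null(seed)) set.seed(seed)
  m <- sum(block_sizes)
  blocks <- lapply(block_sizes, function(sz) {
    if (model == "ar1") rho^abs(outer(seq_len(sz), seq_len(sz), "-"))
    else {
      R <- matrix(rho, sz, sz)
      diag(R) <- 1
      R
    }
  })
  X <- matrix(0, n, m)
  off <- 0L
  for (b in seq_along(blocks)) {
    sz <- block_sizes[b]
    U <- chol(blocks[[b]])
    Z <- matrix(rnorm(n * sz), n, sz)
    X[, off + seq_len(sz)] <- Z %*% U
    off <- off + sz
  }
  freq <- rep(0.5, m)
  if (discretize) {
    f <- stats::runif(m, maf_range[1], maf_range[2])
    q0 <- stats::qnorm((1 - f)^2)
    q1 <- stats::qnorm((1 - f)^2 + 2 * f * (1 - f))
    G <- matrix(0L, n, m)
    for (j in seq_len(m))
      G[, j] <- (X[, j] > q0[j]) + (X[, j] > q1[j])
    X <- G
    freq <- colMeans(G) / 2
  }
  X <- standardize_dosage(X)
  snps <- tibble(snp = paste0("rs", seq_len(m)),
                 chr = as.integer(chr),
                 pos = as.integer(seq_len(m)) * as.integer(pos_spacing),
                 a1 = "A", a2 = "G", freq = freq)
  panel <- new_geno_panel(X, snps)
  panel$true_blocks <- blocks
  panel$block_sizes <- as.integer(block_sizes)
  panel
}

#' Effect-size scenario configuration
#'
#' Describes one of the standard genetic-architecture scenarios:
#' * `"1A"`, `"1B"`, `"1C"` — spike and slab: each SNP causal with
#'   probability `pi` (1e-4, 1e-3, 1e-2 respectively), causal effects
#'   `N(0, h2 / (M pi))`;
#' * `"4"` — mixture of a point mass and three normals with variance
#'   multipliers `c_scales` and mixing proportions `pi_vec`, the common
#'   variance solved so total expected heritability is `h2`;
#' * `"5"` — infinitesimal: every SNP `N(0, h2 / M)`;
#' * `"custom"` — spike and slab with user `pi`, or an exact causal count
#'   `n_causal` (causal SNPs chosen uniformly, slab variance
#'   `h2 / n_causal`).
#'
#' In every scenario the expected sum of squared effects equals `h2`.
#'
#' @param scenario One of `"1A"`, `"1B"`, `"1C"`, `"4"`, `"5"`, `"custom"`.
#' @param M Number of SNPs.
#' @param h2 Total heritability in `(0, 1)`.
#' @param pi Causal proportion for `"custom"`.
#' @param n_causal Exact causal count for `"custom"` (overrides `pi`).
#' @param c_scales,pi_vec Scenario-4 variance multipliers and proportions.
#' @param seed Optional seed.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(scenario = c("1A", "1B", "1C", "4", "5",
                                         "custom"),
                            M, h2 = 0.5, pi = NULL, n_causal = NULL,
                            c_scales = c(1, 0.1, 0.01),
                            pi_vec = c(1e-4, 1e-4, 1e-2), seed = NULL) {
  scenario <- match.arg(scenario)
  if (h2 <= 0 || h2 >= 1) abort("h2 must be in (0, 1)",
                                class = "dprs_config_error")
  if (scenario %in% c("1A", "1B", "1C"))
    pi <- c(`1A` = 1e-4, `1B` = 1e-3, `1C` = 1e-2)[[scenario]]
  if (scenario == "custom" && is.null(pi) && is.null(n_causal))
    abort("custom scenario needs pi or n_causal", class = "dprs_config_error")
  if (scenario == "4") {
    if (length(c_scales) != length(pi_vec))
      abort("c_scales and pi_vec must have equal length",
            class = "dprs_config_error")
    if (sum(pi_vec) > 1) abort("sum(pi_vec) must be <= 1",
                               class = "dprs_config_error")
  }
  structure(list(scenario = scenario, M = as.integer(M), h2 = h2, pi = pi,
                 n_causal = n_causal, c_scales = c_scales, pi_vec = pi_vec,
                 seed = seed),
            class = "scenario_config")
}

#' Simulate true effect sizes under a scenario
#'
#' @param cfg A [scenario_config()].
#' @return Numeric vector of length `M` of true standardized effects;
#'   `E[sum(beta^2)] = h2` by construction.
#' @export
simulate_effects <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  M <- cfg$M
  h2 <- cfg$h2
  beta <- numeric(M)
  if (cfg$scenario == "5") {
    beta <- rnorm(M, 0, sqrt(h2 / M))
  } else if (cfg$scenario == "4") {
    # sigma2 solved from M * sum(pi_i c_i) * sigma2 = h2
    sigma2 <- h2 / (M * sum(cfg$pi_vec * cfg$c_scales))
    comp <- sample(c(0, seq_along(cfg$pi_vec)), M, replace = TRUE,
                   prob = c(1 - sum(cfg$pi_vec), cfg$pi_vec))
    for (k in seq_along(cfg$pi_vec)) {
      sel <- comp == k
      beta[sel] <- rnorm(sum(sel), 0, sqrt(cfg$c_scales[k] * sigma2))
    }
  } else if (!is.null(cfg$n_causal) && cfg$scenario == "custom") {
    idx <- sample.int(M, cfg$n_causal)
    beta[idx] <- rnorm(cfg$n_causal, 0, sqrt(h2 / cfg$n_causal))
  } else {
    pi <- cfg$pi
    causal <- stats::runif(M) < pi
    beta[causal] <- rnorm(sum(causal), 0, sqrt(h2 / (M * pi)))
  }
  beta
}

#' Simulate a phenotype with fixed heritability
#'
#' `y = X beta + epsilon`, standardized to unit variance.  With
#' `exact = TRUE` (default) the genetic and residual components are
#' rescaled (and the noise orthogonalized against the genetic values) so
#' the realized sample variance fraction of the genetic component equals
#' `h2` to machine precision, mirroring fixed-heritability simulation
#' tools; with `exact = FALSE` the noise variance is set to its theoretical
#' value and the realized fraction fluctuates around `h2`.
#'
#' @param X Standardized genotype matrix (or a `geno_panel`).
#' @param beta True effects.
#' @param h2 Target heritability in `[0, 1]`.
#' @param exact Fix the realized variance fraction exactly.
#' @param seed Optional seed.
#' @return Phenotype vector of unit sample variance, with the realized
#'   genetic-variance fraction in `attr(y, "realized_h2")`.
#' @export
simulate_phenotype <- function(X, beta, h2, exact = TRUE, seed = NULL) {
  if (inherits(X, "geno_panel")) X <- X$X
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  g <- drop(X %*% beta)
  vg <- var(g)
  if (h2 == 0 || vg == 0) {
    if (h2 > 0 && vg == 0)
      abort("var(X beta) is zero but h2 > 0", class = "dprs_input_error")
    if (h2 == 0 && any(beta != 0))
      warn("h2 = 0 with nonzero effects: phenotype is pure noise")
    y <- rnorm(n)
    y <- drop(scale(y))
    attr(y, "realized_h2") <- 0
    return(y)
  }
  if (exact) {
    gs <- g / sd(g) * sqrt(h2)
    if (h2 == 1) {
      y <- gs / sqrt(h2)       # pure genetic signal, unit variance
      attr(y, "realized_h2") <- 1
      return(y)
    }
    e <- rnorm(n)
    e <- stats::residuals(stats::lm(e ~ g))   # exactly uncorrelated noise
    es <- e / sd(e) * sqrt(1 - h2)
    y <- gs + es
    attr(y, "realized_h2") <- var(gs) / var(y)
  } else {
    e <- rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
    y <- g + e
    realized <- vg / var(y)
    y <- drop(scale(y))
    attr(y, "realized_h2") <- realized
  }
  y
}

#' Marginal (single-SNP) association scan
#'
#' Computes per-SNP marginal regression coefficients on the standardized
#' scale (equal to the within-sample correlation of the standardized SNP
#' with the standardized phenotype), optionally restricting each SNP to a
#' cohort of individuals, as when different genotyping arrays covered
#' different samples.
#'
#' @param panel A `geno_panel` (or standardized matrix with a `snps`
#'   attribute pattern as produced by [simulate_panel()]).
#' @param y Phenotype vector.
#' @param cohorts Optional list of cohorts, each `list(snps = , rows = )`
#'   with SNP indices and individual indices; cohorts must cover every SNP
#'   exactly once.  Default: one cohort, all SNPs on all individuals.
#' @param n_report Optional misreported sample size recorded in the output
#'   for every SNP (e.g. the nominal study size), regardless of the true
#'   cohort sizes; by default the true cohort size is recorded.
#' @return A summary-statistics tibble (`snp`, `chr`, `pos`, `a1`, `a2`,
#'   `beta_hat`, `n`, `pval`).
#' @export
marginal_gwas <- function(panel, y, cohorts = NULL, n_report = NULL) {
  X <- panel$X
  snps <- panel$snps
  m <- ncol(X)
  if (is.null(cohorts))
    cohorts <- list(list(snps = seq_len(m), rows = seq_len(nrow(X))))
  covered <- sort(unlist(lapply(cohorts, `[[`, "snps")))
  if (!identical(as.integer(covered), seq_len(m)))
    abort("cohorts must cover every SNP exactly once",
          class = "dprs_input_error")
  beta_hat <- numeric(m)
  nvec <- numeric(m)
  for (co in cohorts) {
    rows <- co$rows
    if (length(rows) < 2) abort("cohort smaller than 2 individuals",
                                class = "dprs_input_error")
    Xs <- X[rows, co$snps, drop = FALSE]
    beta_hat[co$snps] <- drop(cor(Xs, y[rows]))
    nvec[co$snps] <- length(rows)
  }
  beta_hat[is.na(beta_hat)] <- 0
  n_out <- if (is.null(n_report)) nvec else rep(n_report, m)
  pval <- 2 * pnorm(-abs(beta_hat) * sqrt(nvec))
  tibble(snp = snps$snp, chr = snps$chr, pos = snps$pos, a1 = snps$a1,
         a2 = snps$a2, beta_hat = beta_hat, n = n_out,
         pval = pmax(pval, .Machine$double.xmin))
}

#' Sample summary statistics directly from the marginal-effect model
#'
#' Draws `beta_hat_b ~ N(R_b beta_b, R_b / N)` per block — the exact
#' sampling distribution the likelihood assumes — bypassing individual-level
#' simulation.  Orders of magnitude faster than cohort simulation; the
#' workhorse for sampler tests.
#'
#' @param blocks List of positive-definite true correlation matrices.
#' @param beta True effects (length = total SNPs).
#' @param N GWAS sample size.
#' @param snps Optional SNP metadata tibble; defaults match
#'   [simulate_panel()] naming.
#' @param seed Optional seed.
#' @return A summary-statistics tibble.
#' @export
direct_sumstats <- function(blocks, beta, N, snps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(blocks, nrow, integer(1))
  m <- sum(sizes)
  stopifnot(length(beta) == m)
  if (is.null(snps))
    snps <- tibble(snp = paste0("rs", seq_len(m)), chr = 1L,
                   pos = seq_len(m) * 1000L, a1 = "A", a2 = "G")
  beta_hat <- numeric(m)
  off <- 0L
  for (b in seq_along(blocks)) {
    sz <- sizes[b]
    R <- blocks[[b]]
    U <- chol(R)
    mu <- drop(R %*% beta[off + seq_len(sz)])
    beta_hat[off + seq_len(sz)] <- mu +
      drop(crossprod(U, rnorm(sz))) / sqrt(N)
    off <- off + sz
  }
  pval <- 2 * pnorm(-abs(beta_hat) * sqrt(N))
  tibble(snp = snps$snp, chr = snps$chr, pos = snps$pos, a1 = snps$a1,
         a2 = snps$a2, beta_hat = beta_hat, n = N,
         pval = pmax(pval, .Machine$double.xmin))
}
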