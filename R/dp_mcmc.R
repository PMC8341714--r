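#' Dirichlet-process mixture prior settings
#'
#' Truncated stick-breaking Dirichlet-process mixture of normals on SNP
#' effect sizes.  Component 0 is an exact point mass at zero (Bayesian
#' variable selection); the base distribution draws component standard
#' deviations uniformly on `(0, u)`, i.e. variances as squared uniforms,
#' avoiding the informativeness issues of inverse-gamma bases.  The model is
#' overparametrized as `beta_i = eta * gamma_i` to improve mixing; only
#' `beta` is reported.
#'
#' @param K Truncation level: maximum number of mixture components
#'   (default 1000).
#' @param u Upper bound of the uniform base distribution on the
#'   standard-deviation scale (default 1; standardized per-SNP effects are
#'   far below 1, so this is effectively uninformative).
#' @param alpha_shape,alpha_rate Gamma hyperprior on the concentration
#'   parameter (default Gamma(0.1, 0.1), weakly informative).
#' @param eta_prior_var Prior variance of the expansion parameter `eta`
#'   (default 1).
#' @return A `dp_prior` object.
#' @export
dp_prior <- function(K = 1000, u = 1, alpha_shape = 0.1, alpha_rate = 0.1,
                     eta_prior_var = 1) {
  if (K < 2) abort("K must be at least 2", class = "dprs_config_error")
  if (u <= 0) abort("u must be positive", class = "dprs_config_error")
  structure(list(K = as.integer(K), u = u, alpha_shape = alpha_shape,
                 alpha_rate = alpha_rate, eta_prior_var = eta_prior_var),
            class = "dp_prior")
}

#' MCMC settings
#'
#' @param n_iter Total Gibbs sweeps (default 1000).
#' @param burn_in Discarded initial sweeps (default 200; must be < n_iter).
#' @param thin Keep every `thin`-th retained sweep.
#' @param seed Master seed; one RNG substream is derived per LD block plus
#'   one global substream, so results do not depend on `n_threads`.
#' @param n_threads Accepted for interface compatibility; block updates are
#'   conditionally independent and executed in a thread-count-invariant
#'   order, so any value yields identical output.
#' @param save_beta_trace Keep the full per-iteration effect trace (memory
#'   heavy; for diagnostics and small problems).
#' @param guard Divergence guard: abort when `max |beta|` exceeds this
#'   (default 1e3).
#' @param update Named list of logical flags `sigma2`, `sticks`, `alpha`,
#'   `eta`; switching one off freezes that part of the state (used for
#'   oracle configurations with known hyperparameters).
#' @param init Named list of optional initial values `sigma2`, `V`, `eta`,
#'   `alpha`, `gamma`, `z`.  The default start is the null model: all SNPs
#'   in the zero component.
#' @return An `mcmc_control` object.
#' @export
mcmc_control <- function(n_iter = 1000, burn_in = 200, thin = 1, seed = 1,
                         n_threads = 1, save_beta_trace = FALSE,
                         guard = 1e3,
                         update = list(), init = list()) {
  if (burn_in >= n_iter) abort("burn_in must be smaller than n_iter",
                               class = "dprs_config_error")
  upd <- list(sigma2 = TRUE, sticks = TRUE, alpha = TRUE, eta = TRUE)
  upd[names(update)] <- update
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 n_threads = as.integer(n_threads),
                 save_beta_trace = save_beta_trace, guard = guard,
                 update = upd, init = init),
            class = "mcmc_control")
}

#' Run the blocked Gibbs sampler on precomputed quadratic forms
#'
#' The low-level fitting routine: consumes [build_block_quadratics()] output
#' and returns posterior summaries.  Most users call [dp_fit()].
#'
#' @param quad A `block_quadratics` object.
#' @param prior A [dp_prior()].
#' @param control An [mcmc_control()].
#' @return A `dp_fit` object; see [dp_fit()].
#' @export
run_block_mcmc <- function(quad, prior = dp_prior(),
                           control = mcmc_control()) {
  stopifnot(inherits(quad, "block_quadratics"), inherits(prior, "dp_prior"),
            inherits(control, "mcmc_control"))
  res <- cpp_run_mcmc(quad$blocks, prior$K, prior$u, prior$alpha_shape,
                      prior$alpha_rate, prior$eta_prior_var,
                      control$n_iter, control$burn_in, control$thin,
                      control$seed, control$init, control$update,
                      control$guard, control$n_threads,
                      control$save_beta_trace)
  if (res$guard_triggered)
    abort(paste0("sampler diverged (max |beta| exceeded ", control$guard,
                 " at iteration ", res$guard_iter, "); the summary ",
                 "statistics are likely inconsistent with the LD ",
                 "reference - consider the regularized likelihood ",
                 "(likelihood_spec(mode = \"regularized\", aN = 0.1))"),
          class = "dprs_divergence_error")
  effects <- tibble(
    snp = quad$snps$snp,
    a1 = quad$snps$a1,
    effect = res$beta_mean,
    nonzero_freq = res$nonzero_freq
  )
  traces <- tibble(
    iteration = seq_len(control$n_iter),
    h2 = res$h2_trace,
    eta = res$eta_trace,
    alpha = res$alpha_trace,
    n_occupied = res$occupied_trace
  )
  structure(list(effects = effects, traces = traces,
                 n_retained = res$n_retained,
                 invariants = list(
                   max_stick_sum_error = res$max_stick_sum_error,
                   max_sigma2_excess = res$max_sigma2_excess,
                   z_gamma_consistent = res$z_gamma_consistent),
                 final_state = res$final_state,
                 beta_trace = if (control$save_beta_trace) res$beta_trace,
                 prior = prior, control = control,
                 likelihood = quad$spec, partition = quad$partition),
            class = "dp_fit")
}

#' Fit the Dirichlet-process effect-size model to summary statistics
#'
#' The main model-fitting entry point: aligns nothing and checks nothing
#' beyond SNP-order agreement (run [qc_filter()] and [align_alleles()]
#' first), precomputes the per-block quadratic forms for the requested
#' likelihood, and runs the blocked Gibbs sampler.
#'
#' @param ss Summary statistics aligned to `ldref` (same SNPs, same order,
#'   same effect alleles).
#' @param ldref An [ld_reference()].
#' @param likelihood A [likelihood_spec()].
#' @param prior A [dp_prior()].
#' @param control An [mcmc_control()].
#' @return A `dp_fit` with elements `effects` (tibble: `snp`, `a1`,
#'   `effect` — posterior-mean standardized effects — and `nonzero_freq`),
#'   `traces` (per-iteration `h2`, `eta`, `alpha`, `n_occupied`
#'   diagnostics; the `h2` column is `beta' R beta`, a heritability-style
#'   diagnostic only), `n_retained`, `invariants`, and the configuration.
#' @seealso [tidy.dp_fit()], [glance.dp_fit()], [autoplot.dp_fit()],
#'   [score_prs()]
#' @export
dp_fit <- function(ss, ldref, likelihood = likelihood_spec(),
                   prior = dp_prior(), control = mcmc_control()) {
  quad <- build_block_quadratics(ldref, ss, likelihood)
  run_block_mcmc(quad, prior, control)
}

#' @export
print.dp_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<dp_fit> %d SNPs, %d blocks, %s likelihood\n",
              nrow(x$effects), nrow(x$partition), x$likelihood$mode))
  cat(sprintf("  %d sweeps (%d retained); mean h2 diagnostic %.4f; mean occupied clusters %.1f\n",
              x$control$n_iter, x$n_retained, g$h2_mean, g$occupied_mean))
  invisible(x)
}

#' Tidy posterior effect estimates
#'
#' @param x A `dp_fit`.
#' @param ... Unused.
#' @return Tibble with one row per SNP: `snp`, `a1`, `effect` (posterior
#'   mean on the standardized scale), `nonzero_freq` (posterior frequency of
#'   assignment to a non-null component).
#' @method tidy dp_fit
#' @export
tidy.dp_fit <- function(x, ...) x$effects

#' One-row fit summary
#'
#' @param x A `dp_fit`.
#' @param ... Unused.
#' @return One-row tibble with counts, post-burn-in means of the
#'   diagnostic traces, and the divergence-guard status.
#' @method glance dp_fit
#' @export
glance.dp_fit <- function(x, ...) {
  keep <- x$traces$iteration > x$control$burn_in
  tibble(
    n_snps = nrow(x$effects),
    n_blocks = nrow(x$partition),
    n_iter = x$control$n_iter,
    n_retained = x$n_retained,
    h2_mean = mean(x$traces$h2[keep], na.rm = TRUE),
    eta_mean = mean(x$traces$eta[keep], na.rm = TRUE),
    alpha_mean = mean(x$traces$alpha[keep], na.rm = TRUE),
    occupied_mean = mean(x$traces$n_occupied[keep], na.rm = TRUE),
    likelihood = x$likelihood$mode
  )
}

#' Diagnostic plots for a fit
#'
#' `type = "trace"` shows the per-iteration heritability-style diagnostic,
#' expansion parameter, concentration parameter and occupied-cluster count;
#' `type = "effects"` shows posterior-mean effects against the posterior
#' non-null assignment frequency.
#'
#' @param object A `dp_fit`.
#' @param type `"trace"` or `"effects"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dp_fit
#' @export
autoplot.dp_fit <- function(object, type = c("trace", "effects"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    long <- tidyr::pivot_longer(object$traces, -"iteration",
                                names_to = "quantity")
    ggplot2::ggplot(long,
                    ggplot2::aes(x = .data$iteration, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = object$control$burn_in,
                          linetype = "dashed", colour = "grey50") +
      ggplot2::facet_wrap(~quantity, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL)
  } else {
    ggplot2::ggplot(object$effects,
                    ggplot2::aes(x = .data$effect,
                                 y = .data$nonzero_freq)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::labs(x = "posterior mean effect (standardized)",
                    y = "posterior non-null frequency")
  }
}

#' @rdname autoplot.dp_fit
#' @param fit A `dp_fit`.
#' @export
plot_traces <- function(fit) autoplot(fit, type = "trace")

# ---- testable conditional-update surfaces -----------------------------------

#' Assignment probabilities for one SNP
#'
#' The normalized component-assignment probabilities used by the sweep for
#' SNP `i` of one block, with the local effect integrated out: with residual
#' `rho_i = v_i - eta * sum_{j != i} B_ij gamma_j`, precision
#' `lambda_k = N eta^2 B_ii + 1 / sigma2_k` and mean
#' `m_k = N eta rho_i / lambda_k`, the log-weights are `log p_0` for the
#' null and `log p_k - log(sigma2_k lambda_k) / 2 + lambda_k m_k^2 / 2`.
#'
#' @param i SNP index within the block (1-based).
#' @param B,v,N Block quadratic summaries.
#' @param eta Current expansion parameter.
#' @param p Component weights (length K).
#' @param sigma2 Component variances (`sigma2[1]` is the null's 0).
#' @param gamma Current within-block effects.
#' @return Numeric vector of K probabilities summing to 1.
#' @export
assignment_weights <- function(i, B, v, N, eta, p, sigma2, gamma) {
  cpp_assignment_weights(i, B, v, N, eta, p, sigma2, gamma)
}

#' Draws from the cluster-variance conditional
#'
#' For an occupied component with `n_k` members and sum of squares `S_k`,
#' the conditional density is proportional to
#' `sigma2^{-(n_k + 1)/2} exp(-S_k / (2 sigma2))` truncated to `(0, u^2]`;
#' empty components draw from the base (squared Uniform(0, u)).
#'
#' @param n_draws Number of draws.
#' @param n_k Component occupancy.
#' @param S_k Sum of squared member effects.
#' @param u Base-distribution bound.
#' @param seed RNG seed.
#' @return Numeric vector of variance draws in `(0, u^2]`.
#' @export
sample_cluster_variances <- function(n_draws, n_k, S_k, u, seed = 1) {
  cpp_sigma2_draws(n_k, S_k, u, n_draws, seed)
}

#' One draw of the stick proportions and weights
#'
#' `V_k ~ Beta(1 + n_k, alpha + sum_{m > k} n_m)` with the last stick fixed
#' at 1, then weights by stick-breaking.
#'
#' @param counts Integer vector of component occupancies (length K).
#' @param alpha Concentration parameter.
#' @param seed RNG seed.
#' @return List with `V` and `p`.
#' @export
sample_sticks <- function(counts, alpha, seed = 1) {
  cpp_sample_sticks(as.integer(counts), alpha, seed)
}

#' Draws from the concentration-parameter conditional
#'
#' `alpha ~ Gamma(shape + K - 1, rate - sum log(1 - V_k))` over the free
#' sticks, with `log(1 - V)` floored at -30.
#'
#' @param n_draws Number of draws.
#' @param V Stick proportions (length K, last equal to 1).
#' @param shape,rate Gamma hyperprior.
#' @param seed RNG seed.
#' @return Numeric vector of draws.
#' @export
sample_alpha <- function(n_draws, V, shape = 0.1, rate = 0.1, seed = 1) {
  cpp_alpha_draws(V, shape, rate, n_draws, seed)
}

#' Stick-breaking weights
#'
#' @param V Stick proportions in `[0, 1]`, last entry 1.
#' @return Weights `p_k = V_k prod_{m < k} (1 - V_m)`.
#' @export
stick_break <- function(V) {
  p <- numeric(length(V))
  remain <- 1
  for (k in seq_along(V)) {
    p[k] <- V[k] * remain
    remain <- remain * (1 - V[k])
  }
  p
}

# ---- oracle baselines -------------------------------------------------------

#' Ridge (infinitesimal-prior) effects
#'
#' Closed-form posterior mean under `beta_j ~ N(0, prior_var)` for every
#' SNP: per block `(N B + I / prior_var)^{-1} N v`.  Used as the
#' known-hyperparameter baseline for the fully polygenic regime.
#'
#' @param quad A `block_quadratics`.
#' @param prior_var Per-SNP prior effect variance (e.g. `h2 / M`).
#' @return Numeric vector of effects in SNP order.
#' @export
ridge_effects <- function(quad, prior_var) {
  unlist(lapply(quad$blocks, function(blk) {
    m <- length(blk$v)
    drop(solve(blk$N * blk$B + diag(1 / prior_var, m), blk$N * blk$v))
  }), use.names = FALSE)
}

#' Spike-and-slab effects with known hyperparameters
#'
#' Gibbs posterior mean under the two-component point-normal model with the
#' true sparsity and slab variance held fixed (no stick, variance,
#' concentration or expansion updates).  Used as the known-hyperparameter
#' baseline for the sparse regime.
#'
#' @param quad A `block_quadratics`.
#' @param pi Causal proportion.
#' @param slab_var Slab variance (e.g. `h2 / (M pi)`).
#' @param n_iter,burn_in,seed Sampler settings.
#' @return Numeric vector of posterior-mean effects in SNP order.
#' @export
spike_slab_effects <- function(quad, pi, slab_var, n_iter = 1000,
                               burn_in = 200, seed = 1) {
  prior <- dp_prior(K = 2, u = max(1, sqrt(slab_var) * 2))
  ctrl <- mcmc_control(
    n_iter = n_iter, burn_in = burn_in, seed = seed,
    update = list(sigma2 = FALSE, sticks = FALSE, alpha = FALSE,
                  eta = FALSE),
    init = list(sigma2 = c(0, slab_var), V = c(1 - pi, 1), eta = 1))
  fit <- run_block_mcmc(quad, prior, ctrl)
  fit$effects$effect
}
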