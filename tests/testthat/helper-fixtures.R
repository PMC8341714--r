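# shared fixtures and independent oracles, all built in code

ar1_block <- function(size, rho = 0.5) rho^abs(outer(seq_len(size),
                                                     seq_len(size), "-"))

ar1_blocks <- function(n_blocks, size, rho = 0.5)
  replicate(n_blocks, ar1_block(size, rho), simplify = FALSE)

# minimal summary-stats tibble for hand-built cases
make_ss <- function(beta_hat, n = 1e4, chr = 1L, pval = 0.5,
                    a1 = "A", a2 = "G") {
  m <- length(beta_hat)
  tibble::tibble(snp = paste0("rs", seq_len(m)), chr = chr,
                 pos = seq_len(m) * 1000L, a1 = a1, a2 = a2,
                 beta_hat = beta_hat, n = n, pval = pval)
}

# Dense enumeration oracle for the two-component (null + fixed-variance
# slab) model under the plain likelihood on a single block: sums over all
# 2^m assignment patterns, integrating the slab effects in closed form.
enum_posterior_mean <- function(R, v, N, s2, p1) {
  m <- length(v)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  logw <- numeric(nrow(patterns))
  means <- matrix(0, nrow(patterns), m)
  for (r in seq_len(nrow(patterns))) {
    S <- patterns[r, ]
    lw <- sum(ifelse(S, log(p1), log(1 - p1)))
    if (any(S)) {
      Lam <- N * R[S, S, drop = FALSE] + diag(1 / s2, sum(S))
      mu <- solve(Lam, N * v[S])
      lw <- lw - 0.5 * (sum(S) * log(s2) +
                          as.numeric(determinant(Lam)$modulus)) +
        0.5 * sum(mu * (Lam %*% mu))
      means[r, S] <- mu
    }
    logw[r] <- lw
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  drop(crossprod(means, w))
}

# batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) trace
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  bs <- floor(n / n_batch)
  bm <- tapply(x[seq_len(n_batch * bs)], rep(seq_len(n_batch), each = bs),
               mean)
  sd(bm) / sqrt(n_batch)
}

# multivariate normal log-density, direct (dense oracle for likelihood
# equivalence checks)
dmvnorm_log <- function(x, mu, Sigma) {
  d <- x - mu
  ch <- chol(Sigma)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, d, transpose = TRUE)^2))
}

# fixed-R LD reference around a list of true block matrices
ldref_of <- function(blocks, ss) {
  dprs::ld_reference_from_blocks(
    blocks, ss[, c("snp", "chr", "pos", "a1", "a2")], n_ref = Inf)
}
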