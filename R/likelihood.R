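#' Covariance kernel entry under sample overlap
#'
#' Entry of the Hadamard factor `H` relating marginal-effect covariance to
#' LD when SNPs were measured on partially overlapping samples:
#' `H_ii = 1 / N_i` and `H_ij = N_s / (N_i N_j)` for `i != j`, where `N_s`
#' is the number of individuals genotyped for both SNPs.
#'
#' @param N_i,N_j Per-SNP sample sizes (> 0).
#' @param N_s Shared sample count, `0 <= N_s <= min(N_i, N_j)`.  Ignored on
#'   the diagonal (`N_i` used).
#' @param diagonal If `TRUE` return the diagonal entry `1 / N_i`.
#' @return The kernel entry.
#' @examples
#' overlap_entry(50000, 40000, 40000)  # 2e-05
#' @export
overlap_entry <- function(N_i, N_j, N_s, diagonal = FALSE) {
  if (any(N_i <= 0))
    abort("sample sizes must be positive", class = "dprs_input_error")
  if (diagonal) return(1 / N_i)
  if (any(N_j <= 0))
    abort("sample sizes must be positive", class = "dprs_input_error")
  if (any(N_s < 0) || any(N_s > pmin(N_i, N_j)))
    abort("shared count must satisfy 0 <= N_s <= min(N_i, N_j)",
          class = "dprs_input_error")
  N_s / (N_i * N_j)
}

#' Implied correlation of marginal effects under the regularized likelihood
#'
#' With the regularized covariance `(R + aN I) / N`, the correlation of the
#' marginal effects of two SNPs is `R_ij / (1 + aN)` instead of
#' `R_ij N_s / sqrt(N_i N_j)`.
#'
#' @param R_ij LD correlation (`|R_ij| <= 1`).
#' @param aN Regularization (`>= 0`), the product of the per-sample ridge
#'   and the sample size.
#' @return `R_ij / (1 + aN)`.
#' @export
effective_correlation <- function(R_ij, aN) {
  if (any(aN < 0)) abort("aN must be nonnegative", class = "dprs_config_error")
  R_ij / (1 + aN)
}

#' Rescale marginal effects by a deflation constant
#'
#' Divides the input effects by `c` to undo deflation from (double) genomic
#' control before model fitting.
#'
#' @param beta_hat Numeric vector of marginal effects.
#' @param c Positive scaling constant (1 = no deflation).
#' @return `beta_hat / c`.
#' @export
rescale_input <- function(beta_hat, c) {
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c <= 0)
    abort("scaling constant c must be a single positive number",
          class = "dprs_config_error")
  beta_hat / c
}

#' Likelihood specification
#'
#' Chooses how observed marginal effects relate to the true joint effects:
#' * `"plain"` — exact likelihood `beta_hat | beta ~ N(R beta, R / N)`,
#'   appropriate when the summary statistics and the LD reference describe
#'   the same individuals;
#' * `"regularized"` (default) — `beta_hat / c | beta ~ N(R beta,
#'   (R + aN I) / N)`, robust to reference-panel mismatch and unknown
#'   sample overlap;
#' * `"overlap"` — `beta_hat | beta ~ N(R beta, R o H)` with the Hadamard
#'   kernel from per-SNP cohort labels and a shared-count rule.
#'
#' @param mode One of `"regularized"`, `"plain"`, `"overlap"`.
#' @param aN Regularization (default 0.1; only used in regularized mode).
#'   `aN = 0`, `c = 1` reduces regularized to plain.
#' @param c Input scaling constant (effects are divided by `c`).
#' @param overlap_labels Tibble `snp`, `label` (overlap mode).
#' @param overlap_rule Tibble `label_i`, `label_j`, `N_s` giving the shared
#'   sample count for every label pair (overlap mode); treated as symmetric.
#' @return A `likelihood_spec`.
#' @export
likelihood_spec <- function(mode = c("regularized", "plain", "overlap"),
                            aN = 0.1, c = 1, overlap_labels = NULL,
                            overlap_rule = NULL) {
  mode <- match.arg(mode)
  if (aN < 0) abort("aN must be >= 0", class = "dprs_config_error")
  if (c <= 0) abort("c must be > 0", class = "dprs_config_error")
  if (mode == "overlap" &&
      (is.null(overlap_labels) || is.null(overlap_rule)))
    abort("overlap mode needs overlap_labels and overlap_rule",
          class = "dprs_config_error")
  structure(list(mode = mode, aN = aN, c = c,
                 overlap_labels = overlap_labels,
                 overlap_rule = overlap_rule),
            class = "likelihood_spec")
}

# symmetric lookup of shared counts for a vector of labels
overlap_ns_matrix <- function(labels, rule) {
  key <- function(a, b) paste(a, b, sep = "\r")
  lut <- setNames(rule$N_s, key(rule$label_i, rule$label_j))
  lut2 <- setNames(rule$N_s, key(rule$label_j, rule$label_i))
  lut <- c(lut, lut2[setdiff(names(lut2), names(lut))])
  m <- length(labels)
  ks <- key(rep(labels, times = m), rep(labels, each = m))
  ns <- lut[ks]
  if (anyNA(ns))
    abort("overlap rule does not cover every label pair",
          class = "dprs_config_error")
  matrix(as.numeric(ns), m, m)
}

# solve(M) via Cholesky with a single automatic ridge retry
chol_inverse <- function(M, what = "kernel") {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    warn(sprintf("%s not positive definite; retrying with 1e-6 ridge", what))
    ch <- chol(M + diag(1e-6, nrow(M)))
  }
  chol2inv(ch)
}

#' Precompute per-block quadratic forms for the sampler
#'
#' Reduces each likelihood variant to the per-block summaries `(B, v, N)`
#' such that the log-likelihood in the joint effects is
#' `N (beta' v - beta' B beta / 2)` up to a constant:
#' plain `B = R`, `v = beta_hat`; regularized `A = (R + aN I)^{-1}`,
#' `B = R A R`, `v = R A (beta_hat / c)`; overlap `C = R o H`,
#' `B = R C^{-1} R / N`, `v = R C^{-1} beta_hat / N`.  `N` is the median
#' per-SNP sample size in the block.
#'
#' @param ldref An `ld_reference`.
#' @param ss Summary statistics aligned to `ldref` SNP order (same ids).
#' @param spec A [likelihood_spec()].
#' @return A `block_quadratics` object: list of per-block
#'   `list(B, R, v, N)` plus metadata.
#' @export
build_block_quadratics <- function(ldref, ss, spec = likelihood_spec()) {
  stopifnot(inherits(ldref, "ld_reference"), inherits(spec, "likelihood_spec"))
  if (!identical(ss$snp, ldref$snps$snp))
    abort("summary statistics are not aligned to the LD reference SNP order",
          class = "dprs_input_error")
  part <- ldref$partition
  beta_t <- rescale_input(ss$beta_hat, spec$c)
  labels <- NULL
  if (spec$mode == "overlap") {
    li <- match(ss$snp, spec$overlap_labels$snp)
    if (anyNA(li)) abort("overlap labels missing for some SNPs",
                         class = "dprs_input_error")
    labels <- spec$overlap_labels$label[li]
  }
  blocks <- vector("list", nrow(part))
  for (b in seq_len(nrow(part))) {
    idx <- part$start[b]:part$end[b]
    R <- ldref$blocks[[b]]
    vb <- beta_t[idx]
    Nb <- median(ss$n[idx])
    blk <- switch(
      spec$mode,
      plain = list(B = R, R = R, v = vb, N = Nb),
      regularized = {
        A <- chol_inverse(R + diag(spec$aN, nrow(R)),
                          sprintf("block %d kernel", b))
        RA <- R %*% A
        list(B = RA %*% R, R = R, v = drop(RA %*% vb), N = Nb)
      },
      overlap = {
        Ns <- overlap_ns_matrix(labels[idx], spec$overlap_rule)
        Ni <- ss$n[idx]
        H <- Ns / outer(Ni, Ni)
        diag(H) <- 1 / Ni
        C <- R * H
        Ci <- chol_inverse(C, sprintf("block %d overlap covariance", b))
        RC <- R %*% Ci
        list(B = (RC %*% R) / Nb, R = R, v = drop(RC %*% vb) / Nb, N = Nb)
      })
    blk$B <- (blk$B + t(blk$B)) / 2
    if (any(!is.finite(blk$B)) || any(!is.finite(blk$v)))
      abort(sprintf("non-finite quadratic forms in block %d", b),
            class = "dprs_numerical_error")
    blocks[[b]] <- blk
  }
  structure(list(blocks = blocks, snps = ldref$snps, partition = part,
                 spec = spec),
            class = "block_quadratics")
}

#' @export
print.block_quadratics <- function(x, ...) {
  cat(sprintf("<block_quadratics> %d SNPs, %d blocks, %s likelihood\n",
              nrow(x$snps), length(x$blocks), x$spec$mode))
  invisible(x)
}
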