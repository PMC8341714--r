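#' Banded squared correlations from a genotype panel
#'
#' Computes r-squared between every SNP pair closer than the window, stored
#' as a band matrix: entry `[d, i]` is the squared sample correlation of SNPs
#' `i` and `i + d`.  A pair is inside the window when its SNP-index distance
#' is at most `window_snps` or its base-pair distance is at most `window_bp`;
#' pairs outside the window are `NA`.
#'
#' @param panel A `geno_panel` (standardized columns).
#' @param window_snps Window as a SNP count (default 256).
#' @param window_bp Window as a base-pair span (default 1 Mb); ignored when
#'   positions are missing.
#' @return An object of class `banded_r2`.
#' @export
banded_r2 <- function(panel, window_snps = 256, window_bp = 1e6) {
  if (window_snps < 1) abort("window must be at least 1 SNP",
                             class = "dprs_config_error")
  X <- panel$X
  n <- nrow(X)
  m <- ncol(X)
  pos <- panel$snps$pos
  use_bp <- !anyNA(pos)
  w_max <- as.integer(window_snps)
  if (use_bp && m > 1) {
    # widest index offset still within the bp window anywhere
    d_bp <- 0L
    for (d in seq_len(m - 1)) {
      if (any(pos[(1 + d):m] - pos[1:(m - d)] <= window_bp)) d_bp <- d
      else if (d > window_snps) break
    }
    w_max <- max(w_max, d_bp)
  }
  w_max <- min(w_max, m - 1L)
  r2 <- matrix(NA_real_, nrow = max(w_max, 1L), ncol = m)
  for (d in seq_len(w_max)) {
    i <- 1:(m - d)
    r <- colSums(X[, i, drop = FALSE] * X[, i + d, drop = FALSE]) / (n - 1)
    val <- r^2
    inside <- (d <= window_snps)
    if (use_bp) {
      in_bp <- (pos[i + d] - pos[i]) <= window_bp
      keep <- inside | in_bp
    } else keep <- rep(inside, length(i))
    val[!keep] <- NA_real_
    r2[d, i] <- val
  }
  structure(list(r2 = r2, window_snps = as.integer(window_snps),
                 window_bp = window_bp, w_max = w_max, m = m,
                 n_ref = n, snps = panel$snps),
            class = "banded_r2")
}

# furthest SNP each SNP is non-ignorably correlated with (within the window)
reach_vector <- function(br2, r2_threshold) {
  m <- br2$m
  reach <- seq_len(m)
  r2 <- br2$r2
  for (d in seq_len(br2$w_max)) {
    i <- 1:(m - d)
    hit <- !is.na(r2[d, i]) & r2[d, i] > r2_threshold
    reach[i][hit] <- pmax(reach[i][hit], i[hit] + d)
  }
  reach
}

# suffix maxima over offsets for one column: S[t] = max_{d >= t} r2[d, j]
suffix_max <- function(col) {
  col[is.na(col)] <- -Inf
  rev(cummax(rev(col)))
}

#' Partition SNPs into approximately independent LD blocks
#'
#' Single left-to-right scan that places a block boundary after SNP `i`
#' whenever no pair within the window straddles the boundary with r-squared
#' above the threshold, so that every SNP's non-ignorable correlations stay
#' inside its own block.  If a block would exceed `max_block_size`, a forced
#' cut is placed at the position minimizing the maximum straddling
#' r-squared, and the violation is logged.
#'
#' @param br2 A [banded_r2()] object.
#' @param r2_threshold Cross-block r-squared bound (default 0.1).
#' @param max_block_size Maximum SNPs per block (default 1024).
#' @return A `block_partition`: tibble with columns `block`, `start`, `end`
#'   (1-based, inclusive), `n_snps`; forced cuts (if any) in
#'   `attr(x, "forced_cuts")` as a tibble of `position`, `max_crossing_r2`.
#' @export
partition_blocks <- function(br2, r2_threshold = 0.1, max_block_size = 1024) {
  m <- br2$m
  reach <- reach_vector(br2, r2_threshold)
  cuts <- integer(0)             # cut after these indices
  forced <- list()
  block_start <- 1L
  furthest <- 0L
  i <- 1L
  while (i < m) {
    furthest <- max(furthest, reach[i])
    if (furthest <= i) {
      cuts <- c(cuts, i)
      block_start <- i + 1L
      furthest <- 0L
    } else if (i - block_start + 1L >= max_block_size) {
      # forced cut: candidate c in [block_start, i]; straddling pairs are
      # (j <= c < k) with j inside the current block and k - j in the window
      idx <- block_start:i
      S <- lapply(idx, function(j) suffix_max(br2$r2[, j]))
      best_c <- NA_integer_
      best_val <- Inf
      for (c in idx) {
        val <- -Inf
        for (jpos in seq_along(idx)) {
          j <- idx[jpos]
          if (j > c) break
          t <- c - j + 1L
          if (t <= br2$w_max) val <- max(val, S[[jpos]][t])
        }
        if (val < best_val) {
          best_val <- val
          best_c <- c
        }
      }
      cuts <- c(cuts, best_c)
      forced[[length(forced) + 1L]] <-
        tibble(position = best_c,
               max_crossing_r2 = if (is.finite(best_val)) best_val else 0)
      block_start <- best_c + 1L
      furthest <- 0L
      i <- best_c                # scan resumes at the new block's first SNP
    }
    i <- i + 1L
  }
  bounds <- c(cuts, m)
  starts <- c(1L, head(bounds, -1) + 1L)
  part <- tibble(block = seq_along(bounds), start = starts, end = bounds,
                 n_snps = bounds - starts + 1L)
  attr(part, "forced_cuts") <- if (length(forced)) bind_rows(forced)
  else tibble(position = integer(0), max_crossing_r2 = numeric(0))
  attr(part, "r2_threshold") <- r2_threshold
  class(part) <- c("block_partition", class(part))
  part
}

#' Validate a block partition against the cross-block r-squared bound
#'
#' @param partition A `block_partition`.
#' @param br2 The [banded_r2()] used to build it.
#' @param r2_threshold The bound (default the partition's own).
#' @return Tibble of violating pairs (`i`, `j`, `r2`); zero rows certifies
#'   the partition.
#' @export
validate_partition <- function(partition, br2,
                               r2_threshold = attr(partition, "r2_threshold")) {
  m <- br2$m
  block_id <- integer(m)
  for (b in seq_len(nrow(partition)))
    block_id[partition$start[b]:partition$end[b]] <- partition$block[b]
  out <- list()
  for (d in seq_len(br2$w_max)) {
    i <- 1:(m - d)
    r2 <- br2$r2[d, i]
    bad <- !is.na(r2) & r2 > r2_threshold & block_id[i] != block_id[i + d]
    if (any(bad)) {
      ii <- i[bad]      # materialize before tibble(): its columns mask `i`
      out[[length(out) + 1L]] <- tibble(i = ii, j = ii + d, r2 = r2[bad])
    }
  }
  if (length(out)) dplyr::arrange(bind_rows(out), .data$i, .data$j)
  else tibble(i = integer(0), j = integer(0), r2 = numeric(0))
}

#' Shrink a sample correlation matrix toward the identity
#'
#' Linear shrinkage `(1 - lambda) R + lambda I`.  With `intensity = "auto"`
#' the intensity is the variance-minimizing linear shrinkage estimate
#' `sum(Var(r_ij)) / sum(r_ij^2)` over off-diagonal entries, with
#' `Var(r_ij)` approximated by `(1 - r_ij^2)^2 / (n_ref - 1)`, clipped to
#' `[0.05, 1]` for `n_ref <= 1000` and `[0.01, 1]` otherwise so the result
#' is always positive definite.
#'
#' @param R Sample correlation matrix.
#' @param n_ref Number of reference individuals behind `R`.
#' @param intensity A value in `[0, 1]`, or `"auto"`.
#' @return The shrunken matrix; the intensity used is in
#'   `attr(x, "lambda")`.
#' @export
shrink_correlation <- function(R, n_ref, intensity = "auto") {
  if (identical(intensity, "auto")) {
    off <- R[upper.tri(R)]
    if (length(off) == 0 || sum(off^2) == 0) {
      lambda <- 1
    } else {
      lambda <- sum((1 - off^2)^2 / (n_ref - 1)) / sum(off^2)
    }
    lam_min <- if (n_ref <= 1000) 0.05 else 0.01
    lambda <- min(max(lambda, lam_min), 1)
  } else {
    lambda <- intensity
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      abort("shrinkage intensity must be in [0, 1] or \"auto\"",
            class = "dprs_config_error")
  }
  out <- (1 - lambda) * R
  diag(out) <- 1
  attr(out, "lambda") <- lambda
  out
}

#' Build a shrunken block-diagonal LD reference
#'
#' Runs the full LD-reference workflow: banded r-squared, block
#' partitioning under the cross-block r-squared bound, per-block sample
#' correlation, and shrinkage toward the identity.
#'
#' @param panel A `geno_panel`.
#' @inheritParams banded_r2
#' @inheritParams partition_blocks
#' @param shrink `"auto"` or a fixed intensity in `[0, 1]`.
#' @return An object of class `ld_reference` with elements `blocks` (list of
#'   shrunken correlation matrices), `partition`, `lambda` (per block),
#'   `snps`, `n_ref`, `violations` (from [validate_partition()]).
#' @export
ld_reference <- function(panel, window_snps = 256, window_bp = 1e6,
                         r2_threshold = 0.1, max_block_size = 1024,
                         shrink = "auto") {
  br2 <- banded_r2(panel, window_snps = window_snps, window_bp = window_bp)
  part <- partition_blocks(br2, r2_threshold = r2_threshold,
                           max_block_size = max_block_size)
  X <- panel$X
  n <- panel$n_ref
  blocks <- vector("list", nrow(part))
  lambda <- numeric(nrow(part))
  for (b in seq_len(nrow(part))) {
    idx <- part$start[b]:part$end[b]
    Rb <- crossprod(X[, idx, drop = FALSE]) / (n - 1)
    diag(Rb) <- 1
    Rb <- shrink_correlation(Rb, n, intensity = shrink)
    lambda[b] <- attr(Rb, "lambda")
    attr(Rb, "lambda") <- NULL
    blocks[[b]] <- Rb
  }
  structure(list(blocks = blocks, partition = part, lambda = lambda,
                 snps = panel$snps, n_ref = n,
                 r2_threshold = r2_threshold,
                 window_snps = window_snps, window_bp = window_bp,
                 violations = validate_partition(part, br2, r2_threshold)),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf(
    "<ld_reference> %d SNPs in %d blocks (n_ref = %d, r2 <= %.3g across blocks)\n",
    nrow(x$snps), length(x$blocks), x$n_ref, x$r2_threshold))
  fc <- attr(x$partition, "forced_cuts")
  if (nrow(fc) > 0)
    cat(sprintf("  %d forced cut(s); max crossing r2 = %.3g\n", nrow(fc),
                max(fc$max_crossing_r2)))
  invisible(x)
}

#' Construct an LD reference directly from known block matrices
#'
#' Mainly for simulations where the true block-diagonal correlation is
#' known: wraps a list of correlation matrices and SNP metadata as an
#' `ld_reference` without re-estimating anything.
#'
#' @param blocks List of (unit-diagonal, positive definite) matrices.
#' @param snps SNP metadata tibble (`snp`, `chr`, `pos`, `a1`, `a2`).
#' @param n_ref Nominal panel size backing the matrices.
#' @return An `ld_reference`.
#' @export
ld_reference_from_blocks <- function(blocks, snps, n_ref = Inf) {
  sizes <- vapply(blocks, nrow, integer(1))
  stopifnot(sum(sizes) == nrow(snps))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  part <- tibble(block = seq_along(blocks), start = starts,
                 end = as.integer(ends), n_snps = sizes)
  attr(part, "forced_cuts") <- tibble(position = integer(0),
                                      max_crossing_r2 = numeric(0))
  attr(part, "r2_threshold") <- 0.1
  class(part) <- c("block_partition", class(part))
  structure(list(blocks = blocks, partition = part,
                 lambda = rep(0, length(blocks)), snps = snps,
                 n_ref = n_ref, r2_threshold = 0.1,
                 window_snps = max(sizes), window_bp = Inf,
                 violations = tibble(i = integer(0), j = integer(0),
                                     r2 = numeric(0))),
            class = "ld_reference")
}
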