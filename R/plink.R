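#' Genotype panel container
#'
#' A light container for a reference or validation genotype panel: the
#' standardized genotype matrix (individuals by SNPs, each column exactly
#' mean 0 and variance 1 after mean imputation of missing entries), per-SNP
#' metadata, and optionally the raw 0/1/2 dosages.
#'
#' @param X Numeric matrix, individuals by SNPs, already standardized.
#' @param snps Tibble with columns `snp`, `chr`, `pos`, `a1`, `a2`, `freq`
#'   (frequency of `a1`).
#' @param dosage Optional integer dosage matrix (counts of `a1`, NA missing).
#' @return An object of class `geno_panel`.
#' @keywords internal
new_geno_panel <- function(X, snps, dosage = NULL) {
  stopifnot(ncol(X) == nrow(snps))
  structure(list(X = X, snps = snps, n_ref = nrow(X), dosage = dosage),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel> %d individuals x %d SNPs\n", x$n_ref,
              ncol(x$X)))
  invisible(x)
}

#' @export
dim.geno_panel <- function(x) dim(x$X)

# mean-impute missing dosages, then center and scale each column to sample
# variance 1; monomorphic columns become all-zero
standardize_dosage <- function(G) {
  G <- apply(G, 2, function(g) {
    miss <- is.na(g)
    if (any(miss)) g[miss] <- mean(g[!miss])
    g
  })
  mu <- colMeans(G)
  G <- sweep(G, 2, mu)
  s <- sqrt(colSums(G^2) / (nrow(G) - 1))
  s[s == 0] <- Inf
  sweep(G, 2, s, "/")
}

# 4 genotypes per byte, low bits first; 2-bit codes of the bed v1.0 format:
# 00 hom first-allele (dosage 2), 01 missing, 10 het, 11 hom second-allele
bed_decode_table <- function() {
  codes <- c(2, NA, 1, 0)
  tab <- matrix(0, nrow = 4, ncol = 256)
  for (b in 0:255) {
    x <- b
    for (k in 1:4) {
      tab[k, b + 1] <- codes[bitwAnd(x, 3L) + 1L]
      x <- bitwShiftR(x, 2L)
    }
  }
  tab
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Reads the binary bed v1.0 SNP-major format together with its bim and fam
#' companions.  Missing genotypes are mean-imputed and columns standardized
#' to mean 0, variance 1; SNPs are sorted by (chromosome, position).
#'
#' @param prefix Path prefix (without extension).
#' @param keep_dosage Keep the raw 0/1/2 dosage matrix alongside the
#'   standardized one (doubles memory).
#' @return A `geno_panel`.  `freq` is the frequency of the bim's first
#'   allele (the counted allele).
#' @export
read_plink <- function(prefix, keep_dosage = FALSE) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "snp", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    abort("not a SNP-major PLINK bed v1.0 file", class = "dprs_input_error")
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) < bytes_per_snp * m)
    abort("truncated bed file", class = "dprs_input_error")
  tab <- bed_decode_table()
  byte_idx <- as.integer(raw) + 1L
  G <- tab[, byte_idx]            # 4 x (bytes_per_snp * m)
  dim(G) <- c(4 * bytes_per_snp, m)
  G <- G[seq_len(n), , drop = FALSE]

  ord <- order(bim$chr, bim$pos)
  bim <- bim[ord, , drop = FALSE]
  G <- G[, ord, drop = FALSE]

  freq <- colMeans(G, na.rm = TRUE) / 2
  snps <- tibble(snp = bim$snp, chr = as.integer(bim$chr),
                 pos = as.integer(bim$pos), a1 = bim$a1, a2 = bim$a2,
                 freq = freq)
  X <- standardize_dosage(G)
  new_geno_panel(X, snps, dosage = if (keep_dosage) G else NULL)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Writes 0/1/2 dosages (counts of `a1`) in bed v1.0 SNP-major format.
#'
#' @param dosage Integer matrix, individuals by SNPs; NA for missing.
#' @param snps Tibble with `snp`, `chr`, `pos`, `a1`, `a2`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(dosage, snps, prefix) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  stopifnot(nrow(snps) == m)
  bim <- data.frame(snps$chr, snps$snp, 0, snps$pos, snps$a1, snps$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(paste0("fam", seq_len(n)), paste0("ind", seq_len(n)),
                    0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # NA -> 1L
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    g <- dosage[, j]
    code <- ifelse(is.na(g), 1L, code_of[as.character(g)])
    code <- c(code, rep(0L, pad))
    quads <- matrix(code, nrow = 4)
    bytes <- quads[1, ] + bitwShiftL(quads[2, ], 2L) +
      bitwShiftL(quads[3, ], 4L) + bitwShiftL(quads[4, ], 6L)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
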