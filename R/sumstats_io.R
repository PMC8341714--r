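#' Read GWAS summary statistics
#'
#' Parses a whitespace- or tab-delimited summary-statistics file with a header
#' into the tidy per-SNP format the rest of the package consumes.  Marginal
#' effects are carried on the standardized-genotype / standardized-phenotype
#' scale: if the file provides only a z-statistic and a sample size, the
#' effect is reconstructed as `z / sqrt(n)`; if it provides per-allele effects
#' together with an allele frequency column, they are rescaled by
#' `sqrt(2 f (1 - f))`.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named character vector mapping the canonical names
#'   `snp, chr, pos, a1, a2, beta, z, n, p, freq` to column names in the
#'   file.  Only the columns present in the file need to be mapped; defaults
#'   cover the conventional header `SNP CHR POS A1 A2 BETA Z N P FREQ`.
#' @param effect_scale `"standardized"` (default) if the effect column is
#'   already per standardized genotype, `"per_allele"` to rescale using the
#'   frequency column.
#'
#' @return A tibble with columns `snp`, `chr`, `pos`, `a1`, `a2`, `beta_hat`,
#'   `n`, `pval` (and `freq` when present).  Rows whose numeric fields fail to
#'   parse are dropped; the count is available via
#'   `attr(x, "n_dropped_unparseable")`.
#' @examples
#' f <- tempfile()
#' writeLines(c("SNP A1 A2 BETA P N", "rs1 A G 0.01 0.5 10000"), f)
#' read_sumstats(f)
#' @export
read_sumstats <- function(path, column_map = NULL,
                          effect_scale = c("standardized", "per_allele")) {
  effect_scale <- match.arg(effect_scale)
  defaults <- c(snp = "SNP", chr = "CHR", pos = "POS", a1 = "A1", a2 = "A2",
                beta = "BETA", z = "Z", n = "N", p = "P", freq = "FREQ")
  map <- defaults
  if (!is.null(column_map)) map[names(column_map)] <- column_map

  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) abort("summary-statistics file is empty",
                             class = "dprs_input_error")
  have <- function(key) map[[key]] %in% names(raw)
  for (key in c("snp", "a1", "a2", "n", "p")) {
    if (!have(key))
      abort(sprintf("required column '%s' (mapped as %s) not found",
                    map[[key]], key),
            class = "dprs_config_error")
  }
  if (!have("beta") && !have("z"))
    abort(sprintf("neither an effect column ('%s') nor a z column ('%s') found",
                  map[["beta"]], map[["z"]]),
          class = "dprs_config_error")

  num <- function(key) suppressWarnings(as.numeric(raw[[map[[key]]]]))
  out <- tibble(
    snp = as.character(raw[[map[["snp"]]]]),
    chr = if (have("chr")) suppressWarnings(as.integer(raw[[map[["chr"]]]])) else NA_integer_,
    pos = if (have("pos")) suppressWarnings(as.integer(raw[[map[["pos"]]]])) else NA_integer_,
    a1 = toupper(as.character(raw[[map[["a1"]]]])),
    a2 = toupper(as.character(raw[[map[["a2"]]]])),
    n = num("n"),
    pval = num("p")
  )
  if (have("freq")) out$freq <- num("freq")
  if (have("beta")) {
    out$beta_hat <- num("beta")
  } else {
    out$beta_hat <- num("z") / sqrt(out$n)
  }
  if (effect_scale == "per_allele") {
    if (!have("freq"))
      abort("per-allele effects need a frequency column to rescale",
            class = "dprs_config_error")
    out$beta_hat <- out$beta_hat * sqrt(2 * out$freq * (1 - out$freq))
  }

  ok <- is.finite(out$beta_hat) & is.finite(out$n) & out$n > 0 &
    is.finite(out$pval)
  n_dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L)
    abort("no parseable summary-statistics records", class = "dprs_input_error")
  out <- dplyr::relocate(out, "snp", "chr", "pos", "a1", "a2", "beta_hat",
                         "n", "pval")
  attr(out, "n_dropped_unparseable") <- n_dropped
  out
}

#' Effective sample size of a case-control GWAS
#'
#' The quantitative-trait-equivalent sample size
#' `4 * n_case * n_control / (n_case + n_control)` used in place of the total
#' count for binary traits.
#'
#' @param n_case,n_control Case and control counts (each > 0).
#' @return The effective sample size (a double), vectorized over its inputs.
#' @examples
#' effective_sample_size(1000, 1000)  # 2000
#' @export
effective_sample_size <- function(n_case, n_control) {
  if (any(!is.finite(n_case)) || any(!is.finite(n_control)) ||
      any(n_case <= 0) || any(n_control <= 0))
    abort("case and control counts must be positive and finite",
          class = "dprs_input_error")
  4 * n_case * n_control / (n_case + n_control)
}

#' Quality-control configuration for summary statistics
#'
#' @param drop_ambiguous Remove strand-ambiguous (A/T and G/C) SNPs.
#' @param drop_indels Remove INDELs and any allele outside A/C/G/T.
#' @param neff_fraction,neff_percentile Remove SNPs whose per-SNP sample size
#'   falls below `neff_fraction` times the `neff_percentile`-th percentile of
#'   sample size (nearest-rank percentile).
#' @param mhc_exclude Remove the MHC region, chromosome 6, 28-34 Mb.
#' @param min_maf Minimum reference-panel minor allele frequency; applied on
#'   the panel side (see [align_alleles()]).
#' @return A `qc_config` list.
#' @export
qc_config <- function(drop_ambiguous = TRUE, drop_indels = TRUE,
                      neff_fraction = 0.67, neff_percentile = 90,
                      mhc_exclude = TRUE, min_maf = 0.01) {
  if (neff_fraction <= 0 || neff_fraction > 1)
    abort("neff_fraction must be in (0, 1]", class = "dprs_config_error")
  if (neff_percentile <= 0 || neff_percentile > 100)
    abort("neff_percentile must be in (0, 100]", class = "dprs_config_error")
  structure(list(drop_ambiguous = drop_ambiguous, drop_indels = drop_indels,
                 neff_fraction = neff_fraction,
                 neff_percentile = neff_percentile,
                 mhc_exclude = mhc_exclude, min_maf = min_maf),
            class = "qc_config")
}

AMBIGUOUS_PAIRS <- c("A/T", "T/A", "C/G", "G/C")
MHC_CHROM <- 6L
MHC_START <- 28e6
MHC_END <- 34e6

#' Quality-control filter for summary statistics
#'
#' Applies, in order: removal of INDELs / non-ACGT alleles, removal of
#' strand-ambiguous pairs (A/T, G/C), removal of SNPs with sample size below
#' `neff_fraction` times the `neff_percentile`-th nearest-rank percentile of
#' sample size over the SNPs surviving the allele filters, and removal of the
#' MHC region (chr6:28-34 Mb).
#'
#' @param ss Summary-statistics tibble from [read_sumstats()].
#' @param cfg A [qc_config()].
#' @return The filtered tibble; per-rule removal counts are stored in
#'   `attr(x, "qc_report")` (a named integer vector).
#' @export
qc_filter <- function(ss, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  if (nrow(ss) == 0L) abort("empty summary statistics",
                            class = "dprs_input_error")
  report <- c(indel = 0L, ambiguous = 0L, low_n = 0L, mhc = 0L,
              duplicate = 0L)

  acgt <- c("A", "C", "G", "T")
  keep <- ss$a1 %in% acgt & ss$a2 %in% acgt & ss$a1 != ss$a2
  if (cfg$drop_indels) {
    report[["indel"]] <- sum(!keep)
    ss <- ss[keep, , drop = FALSE]
  }

  if (cfg$drop_ambiguous && nrow(ss) > 0) {
    amb <- paste(ss$a1, ss$a2, sep = "/") %in% AMBIGUOUS_PAIRS
    report[["ambiguous"]] <- sum(amb)
    ss <- ss[!amb, , drop = FALSE]
  }

  if (nrow(ss) > 0) {
    thr <- cfg$neff_fraction *
      quantile(ss$n, cfg$neff_percentile / 100, type = 1, names = FALSE)
    low <- ss$n < thr
    report[["low_n"]] <- sum(low)
    ss <- ss[!low, , drop = FALSE]
  }

  if (cfg$mhc_exclude && nrow(ss) > 0) {
    in_mhc <- !is.na(ss$chr) & !is.na(ss$pos) & ss$chr == MHC_CHROM &
      ss$pos >= MHC_START & ss$pos <= MHC_END
    report[["mhc"]] <- sum(in_mhc)
    ss <- ss[!in_mhc, , drop = FALSE]
  }

  if (nrow(ss) > 0) {
    dup <- duplicated(ss$snp)
    report[["duplicate"]] <- sum(dup)
    ss <- ss[!dup, , drop = FALSE]
  }

  if (nrow(ss) == 0L)
    abort("all SNPs removed by QC", class = "dprs_input_error")
  attr(ss, "qc_report") <- report
  ss
}

#' Align summary statistics to a reference panel
#'
#' Intersects on SNP id and harmonizes the effect allele with the panel.
#' Where the summary-statistics alleles match the panel's in swapped order,
#' the effect is negated and the alleles exchanged; SNPs whose alleles match
#' in neither orientation are dropped and counted (no strand flipping is
#' attempted; ambiguous SNPs should already have been removed by
#' [qc_filter()]).  SNPs with panel minor allele frequency below `min_maf`
#' are also dropped.  The output rows follow panel order.
#'
#' @param ss QC'd summary-statistics tibble.
#' @param panel A genotype panel from [read_plink()] or [simulate_panel()].
#' @param min_maf Minimum panel MAF (default 0, i.e. no MAF filter here).
#' @return The aligned tibble, ordered as the panel, with counts in
#'   `attr(x, "align_report")`.
#' @export
align_alleles <- function(ss, panel, min_maf = 0) {
  psnp <- panel$snps
  idx <- match(psnp$snp, ss$snp)
  present <- !is.na(idx)
  if (!any(present)) abort("no SNPs shared between summary statistics and panel",
                           class = "dprs_input_error")
  out <- ss[idx[present], , drop = FALSE]
  pan <- psnp[present, , drop = FALSE]
  panel_col <- which(present)

  same <- out$a1 == pan$a1 & out$a2 == pan$a2
  swapped <- out$a1 == pan$a2 & out$a2 == pan$a1
  mismatch <- !(same | swapped)

  out$beta_hat[swapped] <- -out$beta_hat[swapped]
  out$a1[swapped] <- pan$a1[swapped]
  out$a2[swapped] <- pan$a2[swapped]
  out$chr <- pan$chr
  out$pos <- pan$pos

  maf <- if ("freq" %in% names(pan)) pmin(pan$freq, 1 - pan$freq)
  else rep(NA_real_, nrow(pan))
  low_maf <- !mismatch & !is.na(maf) & maf < min_maf

  keep <- !mismatch & !low_maf
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    abort("no SNPs left after allele alignment", class = "dprs_input_error")
  attr(out, "align_report") <- c(
    shared = nrow(pan), flipped = sum(swapped & keep),
    mismatched = sum(mismatch), low_maf = sum(low_maf)
  )
  attr(out, "panel_columns") <- panel_col[keep]
  out
}

#' Score a polygenic risk score on a genotype panel
#'
#' Computes per-individual scores `sum_i effect_i * x_ji` over standardized
#' genotype columns (missing genotypes contribute 0 after mean-centering).
#'
#' @param panel A genotype panel.
#' @param effects Tibble with columns `snp`, `a1`, `effect` (e.g. from
#'   [tidy()] of a fit), or a numeric vector of length `ncol(panel)` aligned
#'   to panel order.
#' @return Numeric vector of length `n_ref` of PRS values.
#' @export
score_prs <- function(panel, effects) {
  X <- panel$X
  if (is.numeric(effects)) {
    if (length(effects) != ncol(X))
      abort("effects length must equal the number of panel SNPs",
            class = "dprs_input_error")
    return(drop(X %*% effects))
  }
  stopifnot(all(c("snp", "a1", "effect") %in% names(effects)))
  idx <- match(effects$snp, panel$snps$snp)
  if (anyNA(idx))
    abort("effects contain SNPs absent from the panel",
          class = "dprs_input_error")
  sgn <- ifelse(effects$a1 == panel$snps$a1[idx], 1,
                ifelse(effects$a1 == panel$snps$a2[idx], -1, NA_real_))
  if (anyNA(sgn))
    abort("effect alleles do not match the panel at some SNPs",
          class = "dprs_input_error")
  w <- numeric(ncol(X))
  w[idx] <- effects$effect * sgn
  drop(X %*% w)
}

#' Write posterior effects as TSV
#'
#' @param effects Tibble with columns `snp`, `a1`, `effect`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  stopifnot(all(c("snp", "a1", "effect") %in% names(effects)))
  readr::write_tsv(effects[, c("snp", "a1", "effect")], path)
  invisible(path)
}
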