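Package: dprs
Title: Polygenic Risk Scores from GWAS Summary Statistics with a
    Dirichlet Process Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian nonparametric estimation of joint SNP effect sizes
    from GWAS summary statistics and an external linkage-disequilibrium
    (LD) reference panel, for polygenic risk score construction.  Places
    a truncated Dirichlet-process mixture prior on per-SNP effect-size
    variances (with a point mass at zero for variable selection) and
    fits it by a blocked Gibbs sampler over approximately independent LD
    blocks.  Includes a robust likelihood for summary-statistics /
    reference-panel mismatch, an LD block partitioning algorithm with a
    cross-block r-squared guarantee, quality control and allele
    alignment for summary statistics, PLINK bed/bim/fam input, a
    genetic-architecture simulator covering spike-and-slab, mixture and
    infinitesimal scenarios, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
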