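#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom asymptotic chi-square test of the observed genotype
#' counts against the Hardy-Weinberg expectations (n p^2, 2 n p q, n q^2)
#' with p estimated from the allele counts. Monomorphic SNPs return p = 1 by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts (vectorised).
#' @return p-value(s) in \[0, 1\].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) stop("at least one genotype is required per SNP")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e_AA <- n * p^2; e_Aa <- 2 * n * p * q; e_aa <- n * q^2
  chi2 <- rep(0, length(n))
  poly <- p > 0 & p < 1
  chi2[poly] <- (n_AA[poly] - e_AA[poly])^2 / e_AA[poly] +
    (n_Aa[poly] - e_Aa[poly])^2 / e_Aa[poly] +
    (n_aa[poly] - e_aa[poly])^2 / e_aa[poly]
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  pval[!poly] <- 1      # monomorphic convention
  pval
}

#' Quality control of a SNP panel
#'
#' Applies, in order and each on the then-current data: (1) removal of
#' individuals with more than `ind_missing_max` missing genotypes, (2)
#' removal of SNPs with call rate below `call_rate_min`, (3) removal of
#' SNPs with minor allele frequency below `maf_min`, (4) removal of SNPs
#' with Hardy-Weinberg test p-value below `hwe_p_min`. SNPs with no
#' non-missing genotype left are removed at the call-rate stage.
#'
#' @param panel a [snp_panel()].
#' @param ind_missing_max maximum tolerated fraction of missing genotypes
#'   per individual (default 0.10).
#' @param call_rate_min minimum per-SNP call rate (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.03).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @return List with elements `panel` (the filtered [snp_panel()]) and
#'   `report`, a `qc_report` with removal counts per stage and the
#'   surviving SNP names.
#' @export
qc_filter <- function(panel, ind_missing_max = 0.10, call_rate_min = 0.90,
                      maf_min = 0.03, hwe_p_min = 1e-6) {
  if (nrow(panel$genotypes) == 0L || ncol(panel$genotypes) == 0L)
    stop("empty panel")
  n_snp_in <- ncol(panel$genotypes)
  n_ind_in <- nrow(panel$genotypes)

  miss_frac <- rowMeans(is.na(panel$genotypes))
  keep_ind <- miss_frac <= ind_missing_max
  n_ind_rm <- sum(!keep_ind)
  if (!any(keep_ind)) stop("empty panel: all individuals removed by QC")
  panel <- panel[which(keep_ind), ]

  call_rate <- colMeans(!is.na(panel$genotypes))
  keep_cr <- call_rate >= call_rate_min & call_rate > 0
  n_cr_rm <- sum(!keep_cr)
  if (!any(keep_cr)) stop("empty panel: all SNPs removed by call-rate filter")
  panel <- panel[, which(keep_cr)]

  p <- allele_freq(panel)
  maf <- pmin(p, 1 - p)
  keep_maf <- maf >= maf_min
  n_maf_rm <- sum(!keep_maf)
  if (!any(keep_maf)) stop("empty panel: all SNPs removed by MAF filter")
  panel <- panel[, which(keep_maf)]

  cnt <- genotype_counts(panel)
  hwe_p <- hwe_test(cnt[, "n_AA"], cnt[, "n_Aa"], cnt[, "n_aa"])
  keep_hwe <- hwe_p >= hwe_p_min
  n_hwe_rm <- sum(!keep_hwe)
  if (!any(keep_hwe)) stop("empty panel: all SNPs removed by HWE filter")
  panel <- panel[, which(keep_hwe)]

  report <- structure(list(
    n_individuals_in = n_ind_in,
    n_snps_in = n_snp_in,
    n_individuals_removed = n_ind_rm,
    n_snps_removed_callrate = n_cr_rm,
    n_snps_removed_maf = n_maf_rm,
    n_snps_removed_hwe = n_hwe_rm,
    surviving_snp_names = panel$snp_map$name
  ), class = "qc_report")
  list(panel = panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n",
      "  individuals removed (missingness): ", x$n_individuals_removed, "\n",
      "  SNPs removed by call rate:         ", x$n_snps_removed_callrate, "\n",
      "  SNPs removed by MAF:               ", x$n_snps_removed_maf, "\n",
      "  SNPs removed by HWE:               ", x$n_snps_removed_hwe, "\n",
      "  SNPs surviving:                    ", length(x$surviving_snp_names),
      " of ", x$n_snps_in, "\n", sep = "")
  invisible(x)
}
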