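#' SNP genotype panel
#'
#' Container for an n x p matrix of additive genotype codes together with the
#' SNP map and individual identifiers. Genotypes are coded 1, 0 and -1 for
#' AA, Aa and aa respectively, where "A" is a per-SNP reference allele
#' (by default the major allele). Missing genotypes are stored as `NA`.
#'
#' @param genotypes numeric matrix, n individuals x p SNPs, entries in
#'   \{1, 0, -1\} or `NA` for missing.
#' @param snp_map data.frame with columns `name` (character), `chrom`
#'   (integer) and `pos` (numeric, base pairs or map units), one row per SNP.
#'   Within a chromosome, positions must be non-decreasing.
#' @param individual_ids character vector of length n.
#' @return An object of class `snp_panel` with elements `genotypes`,
#'   `snp_map` and `individual_ids`.
#' @export
snp_panel <- function(genotypes, snp_map, individual_ids) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(1, 0, -1)))
    stop("non-missing genotype codes must be 1, 0 or -1")
  snp_map <- as.data.frame(snp_map, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "pos")
  if (!all(need %in% names(snp_map)))
    stop("snp_map must have columns name, chrom, pos")
  if (nrow(snp_map) != ncol(genotypes))
    stop("snp_map rows (", nrow(snp_map), ") != genotype columns (",
         ncol(genotypes), ")")
  if (length(individual_ids) != nrow(genotypes))
    stop("individual_ids length (", length(individual_ids),
         ") != genotype rows (", nrow(genotypes), ")")
  snp_map$name <- as.character(snp_map$name)
  snp_map$chrom <- as.integer(snp_map$chrom)
  snp_map$pos <- as.numeric(snp_map$pos)
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (is.unsorted(p)) stop("positions on chromosome ", ch,
                             " are not non-decreasing")
  }
  dimnames(genotypes) <- list(as.character(individual_ids), snp_map$name)
  structure(list(genotypes = genotypes, snp_map = snp_map,
                 individual_ids = as.character(individual_ids)),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  nmis <- sum(is.na(x$genotypes))
  cat("snp_panel: ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " SNPs (", nmis, " missing genotypes)\n", sep = "")
  invisible(x)
}

#' @export
dim.snp_panel <- function(x) dim(x$genotypes)

#' Subset a SNP panel
#'
#' @param x a [snp_panel()].
#' @param i individual (row) index, any standard matrix index.
#' @param j SNP (column) index.
#' @param ... unused.
#' @return A `snp_panel` restricted to the selected individuals and SNPs.
#' @export
`[.snp_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$genotypes))
  if (missing(j)) j <- seq_len(ncol(x$genotypes))
  snp_panel(x$genotypes[i, j, drop = FALSE],
            x$snp_map[j, , drop = FALSE],
            x$individual_ids[i])
}

#' Reference-allele frequency of each SNP
#'
#' Computes, per SNP, the frequency of the "A" allele (the allele whose
#' homozygote is coded +1): p_j = (2 n_AA + n_Aa) / (2 n_nonmissing).
#' SNPs with no non-missing genotype get `NA` and should be excluded from
#' any downstream model.
#'
#' @param panel a [snp_panel()].
#' @return Numeric vector of length p with values in \[0, 1\] (or `NA`).
#' @export
allele_freq <- function(panel) {
  g <- panel$genotypes
  n_obs <- colSums(!is.na(g))
  s <- colSums(g, na.rm = TRUE)           # sum of codes = n_AA - n_aa
  n_het <- colSums(g == 0, na.rm = TRUE)
  n_AA <- (s + (n_obs - n_het)) / 2
  p <- (2 * n_AA + n_het) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  unname(p)
}

#' Per-SNP genotype counts
#'
#' @param panel a [snp_panel()].
#' @return Integer matrix p x 3 with columns `n_AA`, `n_Aa`, `n_aa`.
#' @export
genotype_counts <- function(panel) {
  g <- panel$genotypes
  cbind(n_AA = colSums(g == 1, na.rm = TRUE),
        n_Aa = colSums(g == 0, na.rm = TRUE),
        n_aa = colSums(g == -1, na.rm = TRUE))
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing genotype by the per-SNP mean code 2 p_j - 1, the
#' expectation of the \{1,0,-1\} code at allele frequency p_j. The model
#' fitting functions assume a complete genotype matrix; this is the
#' package's imputation rule for genotypes that survive QC.
#'
#' @param panel a [snp_panel()].
#' @return A numeric n x p matrix with no missing values.
#' @export
impute_genotypes <- function(panel) {
  g <- panel$genotypes
  miss <- is.na(g)
  if (any(miss)) {
    p <- allele_freq(panel)
    if (anyNA(p)) stop("cannot impute SNPs with all genotypes missing")
    fill <- matrix(2 * p - 1, nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
    g[miss] <- fill[miss]
    n_imp <- sum(miss)
    message("mean-imputed ", n_imp, " missing genotype(s)")
  }
  g
}

#' Phenotype vector
#'
#' A continuous trait (one value per individual) with identifiers, e.g.
#' estimated breeding values used as pseudo-phenotypes.
#'
#' @param values numeric vector of trait values.
#' @param individual_ids character vector, same length as `values`.
#' @return An object of class `phenotype_vector`.
#' @export
phenotype_vector <- function(values, individual_ids) {
  if (length(values) != length(individual_ids))
    stop("values and individual_ids differ in length")
  structure(list(values = as.numeric(values),
                 individual_ids = as.character(individual_ids)),
            class = "phenotype_vector")
}

#' Align a phenotype vector with a SNP panel
#'
#' Joins on individual id; individuals of the panel without a (finite)
#' phenotype are dropped with a message stating the count. The result is a
#' panel and phenotype in identical row order.
#'
#' @param pheno a [phenotype_vector()].
#' @param panel a [snp_panel()].
#' @return List with elements `panel` (subset, reordered) and `y`
#'   (numeric vector aligned to the panel rows).
#' @export
align_phenotype <- function(pheno, panel) {
  idx <- match(panel$individual_ids, pheno$individual_ids)
  ok <- !is.na(idx) & is.finite(pheno$values[idx])
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message("dropped ", n_drop, " individual(s) without phenotype")
  if (!any(ok)) stop("no individual has both genotype and phenotype")
  list(panel = panel[which(ok), ], y = pheno$values[idx[ok]])
}
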