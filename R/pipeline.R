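#' Configuration of a two-stage association run
#'
#' Inputs may be given as file paths (`ped`/`map`/`pheno`/`pedigree`) or
#' as in-memory objects (`panel`, `phenotypes`, `pedigree_table`).
#'
#' @param ped,map,pheno,pedigree input file paths (PLINK-style text
#'   genotypes, TSV phenotype, CSV pedigree), or `NULL` when in-memory
#'   objects are supplied.
#' @param panel a [snp_panel()] (alternative to `ped`/`map`).
#' @param phenotypes a [phenotype_vector()] (alternative to `pheno`).
#' @param pedigree_table a [pedigree_table()] (alternative to `pedigree`).
#' @param ind_missing_max,call_rate_min,maf_min,hwe_p_min QC thresholds,
#'   see [qc_filter()].
#' @param top_k SNPs retained by the SMMA prescreen (default 500).
#' @param n_perm permutations for the significance thresholds
#'   (default 1000).
#' @param alpha significance level (default 0.05).
#' @param meml a [meml_config()].
#' @param seed integer seed for the permutation thresholds.
#' @param out_dir optional output directory for result TSVs and the run
#'   manifest.
#' @return A `gwas_config` list.
#' @export
gwas_config <- function(ped = NULL, map = NULL, pheno = NULL,
                        pedigree = NULL, panel = NULL, phenotypes = NULL,
                        pedigree_table = NULL, ind_missing_max = 0.10,
                        call_rate_min = 0.90, maf_min = 0.03,
                        hwe_p_min = 1e-6, top_k = 500, n_perm = 1000,
                        alpha = 0.05, meml = meml_config(), seed = 1,
                        out_dir = NULL) {
  if (top_k < 1) stop("top_k must be at least 1")
  for (f in c(ped, map, pheno, pedigree))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  if (is.null(panel) && (is.null(ped) || is.null(map)))
    stop("either panel or ped+map paths are required")
  if (is.null(phenotypes) && is.null(pheno))
    stop("either phenotypes or a pheno path is required")
  if (is.null(pedigree_table) && is.null(pedigree))
    stop("either pedigree_table or a pedigree path is required")
  structure(list(ped = ped, map = map, pheno = pheno, pedigree = pedigree,
                 panel = panel, phenotypes = phenotypes,
                 pedigree_table = pedigree_table,
                 ind_missing_max = ind_missing_max,
                 call_rate_min = call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, top_k = top_k, n_perm = n_perm,
                 alpha = alpha, meml = meml, seed = seed,
                 out_dir = out_dir), class = "gwas_config")
}

#' Run the two-stage multi-SNP association analysis
#'
#' Stage 0: quality control (individual missingness, SNP call rate, MAF,
#' HWE). Stage 1: REML null fit and genome-wide SMMA scan; the `top_k`
#' SNPs with the smallest p-values are retained. Stage 2: MEML fit of the
#' retained SNPs; permutation thresholds for both the SMMA -log10 p and
#' the MEML per-SNP heritability; the table of SNPs whose heritability
#' exceeds the threshold.
#'
#' @param config a [gwas_config()].
#' @return List with `qc_report`, `vc` (null variance components), `smma`
#'   (full scan table), `prescreen_idx`, `meml` (the `meml_fit`),
#'   `meml_table` (snp, chrom, pos, gamma, h2, significant),
#'   `thresholds` (`h2` and `logp` permutation results), `significant`
#'   (rows of `meml_table` above threshold) and `manifest` (seeds,
#'   thresholds and counts at every stage). If `config$out_dir` is set the
#'   tables and a JSON manifest are also written there.
#' @export
run_two_stage <- function(config) {
  stopifnot(inherits(config, "gwas_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  panel <- stage("read_genotypes",
                 config$panel %||% read_plink_text(config$ped, config$map))
  pheno <- stage("read_phenotypes",
                 config$phenotypes %||% read_phenotype_tsv(config$pheno))
  ped <- stage("read_pedigree",
               config$pedigree_table %||% read_pedigree_csv(config$pedigree))

  qc <- stage("qc", qc_filter(panel, config$ind_missing_max,
                              config$call_rate_min, config$maf_min,
                              config$hwe_p_min))
  aligned <- stage("align", align_phenotype(pheno, qc$panel))
  panel <- aligned$panel; y <- aligned$y

  A_full <- stage("kinship", a_matrix(ped))
  idx <- match(panel$individual_ids, A_full$id_order)
  if (anyNA(idx))
    stop("stage [kinship] failed: individuals missing from pedigree: ",
         paste(utils::head(panel$individual_ids[is.na(idx)], 5),
               collapse = ", "))
  A <- as_a_matrix(A_full$values[idx, idx, drop = FALSE],
                   panel$individual_ids)

  vc <- stage("reml", fit_null_reml(y, A))
  smma <- stage("smma", smma_scan(y, panel, A, vc))
  k <- min(config$top_k, sum(smma$tested))
  if (k < config$top_k)
    warning("top_k exceeds the number of tested SNPs; using all ", k)
  keep <- stage("prescreen", prescreen(smma, k))
  sub <- panel[, keep]

  fit <- stage("meml", fit_meml(y, sub, A, config = config$meml))
  thr_h2 <- stage("permutation_h2", permutation_threshold(
    y, sub, A, statistic = "h2", n_perm = config$n_perm,
    alpha = config$alpha, seed = config$seed, config = config$meml))
  thr_logp <- stage("permutation_logp", permutation_threshold(
    y, panel, A, statistic = "logp", n_perm = config$n_perm,
    alpha = config$alpha, seed = config$seed + 1L))

  meml_table <- data.frame(
    snp = sub$snp_map$name, chrom = sub$snp_map$chrom,
    pos = sub$snp_map$pos, gamma = fit$gamma, h2 = fit$h2,
    significant = as.integer(fit$h2 > thr_h2$threshold))
  significant <- meml_table[meml_table$significant == 1L, , drop = FALSE]
  significant <- significant[order(-significant$h2), , drop = FALSE]

  manifest <- list(
    package_version = as.character(utils::packageVersion("memlgwas")),
    seed = config$seed, alpha = config$alpha, n_perm = config$n_perm,
    top_k = config$top_k,
    meml = list(a = config$meml$a, b = config$meml$b,
                tol = config$meml$tol, max_iter = config$meml$max_iter),
    qc = list(individuals_removed = qc$report$n_individuals_removed,
              snps_removed_callrate = qc$report$n_snps_removed_callrate,
              snps_removed_maf = qc$report$n_snps_removed_maf,
              snps_removed_hwe = qc$report$n_snps_removed_hwe),
    counts = list(n_individuals = length(y),
                  n_snps_tested = sum(smma$tested),
                  n_prescreened = length(keep),
                  n_significant = nrow(significant)),
    variance_components = list(sigma_g2 = vc$sigma_g2,
                               sigma_e2 = vc$sigma_e2),
    thresholds = list(h2 = thr_h2$threshold, logp = thr_logp$threshold),
    meml_converged = fit$converged, meml_iterations = fit$n_iterations)

  out <- list(qc_report = qc$report, vc = vc, smma = smma,
              prescreen_idx = keep, meml = fit, meml_table = meml_table,
              thresholds = list(h2 = thr_h2, logp = thr_logp),
              significant = significant, manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    write_smma_tsv(smma, o("smma.tsv"))
    utils::write.table(meml_table, o("meml.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(significant, o("significant.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_permutation_tsv(thr_h2, o("perm_h2.tsv"))
    write_permutation_tsv(thr_logp, o("perm_logp.tsv"))
    jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  out
}

#' Annotate significant SNPs with the nearest feature of a BED file
#'
#' Convenience lookup: for each SNP, the nearest feature of a
#' user-provided BED file (chrom, start, end, name) within `window` base
#' pairs. Purely positional; no annotation source is bundled.
#'
#' @param table data.frame with `chrom` and `pos` columns (e.g. the
#'   significant-SNP table of [run_two_stage()]).
#' @param bed_path path to a BED file.
#' @param window maximum distance in base pairs (default 200000).
#' @return The table with `nearest_gene` and `gene_distance` columns
#'   (`NA` when nothing is within the window; distance 0 when inside the
#'   feature).
#' @export
annotate_nearest_gene <- function(table, bed_path, window = 2e5) {
  bed <- utils::read.table(bed_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  bed$chrom <- as.character(bed$chrom)
  table$nearest_gene <- NA_character_
  table$gene_distance <- NA_real_
  for (i in seq_len(nrow(table))) {
    cand <- bed[bed$chrom == as.character(table$chrom[i]), , drop = FALSE]
    if (!nrow(cand)) next
    dist <- pmax(0, pmax(cand$start - table$pos[i],
                         table$pos[i] - cand$end))
    j <- which.min(dist)
    if (dist[j] <= window) {
      table$nearest_gene[i] <- cand$name[j]
      table$gene_distance[i] <- dist[j]
    }
  }
  table
}

#' Needle plot of per-SNP heritabilities
#'
#' Per-chromosome needle plot of the MEML SNP heritabilities with an
#' optional horizontal threshold line.
#'
#' @param fit a `meml_fit` with a `snp_map`, or a data.frame with
#'   `chrom` and `h2` columns.
#' @param threshold optional genome-wide threshold to draw.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_snp_h2 <- function(fit, threshold = NULL, ...) {
  if (inherits(fit, "meml_fit")) {
    stopifnot(!is.null(fit$snp_map))
    d <- data.frame(chrom = fit$snp_map$chrom, h2 = fit$h2)
  } else d <- fit
  x <- seq_len(nrow(d))
  graphics::plot(x, d$h2, type = "h", xlab = "SNP (genome order)",
                 ylab = expression(h[j]^2), ...)
  br <- which(diff(d$chrom) != 0)
  if (length(br)) graphics::abline(v = br + 0.5, lty = 3, col = "grey60")
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(NULL)
}

#' Read a QTL-MAS-style workshop dataset
#'
#' Optional loader for the common workshop text layout: a genotype file
#' with one row per individual (id followed by two allele columns per SNP,
#' alleles coded 1/2, 0 missing), a phenotype file (id, value) and
#' optionally a pedigree file (id, sire, dam; 0 unknown), all
#' whitespace-delimited without headers. SNPs are placed on consecutive
#' chromosomes of `snps_per_chromosome` loci.
#'
#' @param genotype_path,phenotype_path,pedigree_path input files
#'   (`pedigree_path` optional).
#' @param snps_per_chromosome loci per chromosome (default 1000).
#' @return List with `panel`, `phenotypes` and (if given) `pedigree`.
#' @export
read_qtlmas <- function(genotype_path, phenotype_path,
                        pedigree_path = NULL, snps_per_chromosome = 1000) {
  g <- utils::read.table(genotype_path, header = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  ids <- g[[1L]]
  al <- as.matrix(g[, -1L, drop = FALSE])
  if (ncol(al) %% 2L != 0L)
    stop("genotype file must have two allele columns per SNP")
  p <- ncol(al) %/% 2L
  a1 <- al[, seq(1L, 2L * p, 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * p, 2L), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  code <- (a1 == "1") + (a2 == "1") - 1
  code[miss] <- NA_real_
  chrom <- (seq_len(p) - 1L) %/% snps_per_chromosome + 1L
  idx <- (seq_len(p) - 1L) %% snps_per_chromosome + 1L
  panel <- snp_panel(code,
                     data.frame(name = paste0("c", chrom, "s", idx),
                                chrom = chrom, pos = idx), ids)
  ph <- utils::read.table(phenotype_path, header = FALSE,
                          stringsAsFactors = FALSE)
  out <- list(panel = panel,
              phenotypes = phenotype_vector(as.numeric(ph[[2L]]),
                                            as.character(ph[[1L]])))
  if (!is.null(pedigree_path)) {
    pd <- utils::read.table(pedigree_path, header = FALSE,
                            colClasses = "character")
    out$pedigree <- pedigree_table(pd[[1L]], pd[[2L]], pd[[3L]])
  }
  out
}
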