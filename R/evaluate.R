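#' Count detections and false positives against the true QTL
#'
#' A significant SNP within one locus (index distance on the SNP grid, same
#' chromosome) of a true QTL detects that QTL; each QTL is counted at most
#' once per replicate. Significant SNPs not within one locus of any QTL are
#' false positives.
#'
#' @param sig_cols integer global column indices of significant SNPs.
#' @param true_qtl QTL table with `chrom`, `snp_index` and global
#'   `snp_col`.
#' @param snps_per_chromosome grid size used to map global columns to
#'   within-chromosome indices.
#' @return List with `n_detected` and `n_false_positive`.
#' @export
count_detections <- function(sig_cols, true_qtl, snps_per_chromosome) {
  if (!length(sig_cols))
    return(list(n_detected = 0L, n_false_positive = 0L))
  sig_chrom <- (sig_cols - 1L) %/% snps_per_chromosome + 1L
  sig_idx <- (sig_cols - 1L) %% snps_per_chromosome + 1L
  hits_qtl <- logical(nrow(true_qtl))
  is_fp <- rep(TRUE, length(sig_cols))
  for (q in seq_len(nrow(true_qtl))) {
    near <- sig_chrom == true_qtl$chrom[q] &
      abs(sig_idx - true_qtl$snp_index[q]) <= 1L
    if (any(near)) hits_qtl[q] <- TRUE
    is_fp[near] <- FALSE
  }
  list(n_detected = sum(hits_qtl), n_false_positive = sum(is_fp))
}

#' Power and false-positive rate of association methods over replicates
#'
#' Runs, per simulated replicate, each requested association method with
#' its permutation significance threshold, and aggregates power
#' (detected QTL / total simulated QTL) and false-positive rate
#' (false-positive SNPs / non-QTL loci, where each QTL masks 3 loci:
#' itself and its two neighbours).
#'
#' Built-in methods: `"smma"` (genome-wide single-marker mixed-model scan,
#' statistic -log10 p) and `"meml"` (MEML fit of the `top_k` SNPs
#' prescreened by SMMA, statistic h2). A method can also be supplied as a
#' function `f(replicate, A)` returning significant global SNP column
#' indices (used for mock methods in validation).
#'
#' @param config a [sim_config()].
#' @param n_replicates number of simulated replicates.
#' @param methods character vector among "smma", "meml", or a named list
#'   mixing those names and functions.
#' @param top_k SNPs kept by the prescreen for MEML (default 500).
#' @param n_perm permutations per threshold (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer master seed; replicate r uses seed + r.
#' @param meml_cfg a [meml_config()].
#' @return A named list of `power_fpr_report` objects, one per method,
#'   each with `power`, `fpr`, `detected_qtl_count`, `total_qtl_count`,
#'   `false_positive_count`, `non_qtl_locus_count`, `n_replicates`
#'   (effective), and `method`.
#' @export
evaluate_replicates <- function(config, n_replicates, methods = c("smma",
                                "meml"), top_k = 500, n_perm = 1000,
                                alpha = 0.05, seed = 1,
                                meml_cfg = meml_config()) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  if (!is.list(methods)) {
    methods <- stats::setNames(as.list(methods), methods)
  }
  total_snps <- config$n_chromosomes * config$snps_per_chromosome
  n_qtl <- nrow(config$qtl_spec)
  non_qtl <- total_snps - 3L * n_qtl
  acc <- lapply(methods, function(m)
    list(det = 0L, fp = 0L, reps = 0L))

  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- (seed %||% 0) + r
    rep_ <- simulate_replicate(cfg_r)
    A <- a_matrix(rep_$pedigree)
    y <- rep_$y

    shared <- new.env()
    run_method <- function(m, label) {
      if (is.function(m)) return(m(rep_, A))
      if (identical(m, "smma")) {
        sc <- get_smma(shared, y, rep_$panel, A)
        thr <- permutation_threshold(y, rep_$panel, A, statistic = "logp",
                                     n_perm = n_perm, alpha = alpha,
                                     seed = (cfg_r$seed * 1009L) %% 2147480L + 7L)
        which(-log10(sc$p) > thr$threshold & sc$tested)
      } else if (identical(m, "meml")) {
        sc <- get_smma(shared, y, rep_$panel, A)
        keep <- prescreen(sc, min(top_k, sum(sc$tested)))
        sub <- rep_$panel[, keep]
        fit <- fit_meml(y, sub, A, config = meml_cfg)
        thr <- permutation_threshold(y, sub, A, statistic = "h2",
                                     n_perm = n_perm, alpha = alpha,
                                     seed = (cfg_r$seed * 1009L) %% 2147480L + 13L,
                                     config = meml_cfg)
        keep[fit$h2 > thr$threshold]
      } else stop("unknown method: ", label)
    }

    for (nm in names(methods)) {
      sig <- tryCatch(run_method(methods[[nm]], nm), error = function(e) e)
      if (inherits(sig, "error")) {
        message("replicate ", r, ", method ", nm, " failed: ",
                conditionMessage(sig), " (replicate skipped)")
        next
      }
      cnt <- count_detections(sig, rep_$true_qtl,
                              config$snps_per_chromosome)
      acc[[nm]]$det <- acc[[nm]]$det + cnt$n_detected
      acc[[nm]]$fp <- acc[[nm]]$fp + cnt$n_false_positive
      acc[[nm]]$reps <- acc[[nm]]$reps + 1L
    }
  }

  out <- lapply(names(methods), function(nm) {
    a <- acc[[nm]]
    structure(list(
      method = nm, n_replicates = a$reps,
      detected_qtl_count = a$det,
      total_qtl_count = n_qtl * a$reps,
      power = if (a$reps > 0) a$det / (n_qtl * a$reps) else NA_real_,
      false_positive_count = a$fp,
      non_qtl_locus_count = non_qtl * a$reps,
      fpr = if (a$reps > 0) a$fp / (non_qtl * a$reps) else NA_real_
    ), class = "power_fpr_report")
  })
  stats::setNames(out, names(methods))
}

# cache the SMMA scan so smma and meml share stage 1 within a replicate
get_smma <- function(env, y, panel, A) {
  if (is.null(env$smma)) env$smma <- smma_scan(y, panel, A)
  env$smma
}

#' @export
print.power_fpr_report <- function(x, ...) {
  cat("power_fpr_report [", x$method, "]: power = ",
      format(100 * x$power, digits = 4), "% (", x$detected_qtl_count, "/",
      x$total_qtl_count, "), FPR = ", format(100 * x$fpr, digits = 4),
      "% (", x$false_positive_count, "/", x$non_qtl_locus_count, ") over ",
      x$n_replicates, " replicate(s)\n", sep = "")
  invisible(x)
}

#' Write a power/FPR report table
#' @param reports named list of `power_fpr_report` objects.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_power_fpr_tsv <- function(reports, path) {
  d <- do.call(rbind, lapply(reports, function(x)
    data.frame(method = x$method, n_replicates = x$n_replicates,
               detected = x$detected_qtl_count,
               total_qtl = x$total_qtl_count, power = x$power,
               false_positives = x$false_positive_count,
               non_qtl_loci = x$non_qtl_locus_count, fpr = x$fpr)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
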