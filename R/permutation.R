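#' Genome-wide significance threshold by phenotype permutation
#'
#' Shuffles the phenotype vector across individuals (breaking both the
#' genotype-phenotype and the pedigree-phenotype links), reruns the chosen
#' association procedure on the same SNP set, records the maximum per-SNP
#' statistic of each permutation, and returns the empirical (1 - alpha)
#' quantile of those maxima as the genome-wide threshold.
#'
#' The SNP set is held fixed across permutations (for a two-stage analysis
#' the prescreen is not re-run per permutation). A failed permutation fit
#' is retried with a fresh shuffle at most 3 times.
#'
#' @param y numeric phenotype vector.
#' @param panel a [snp_panel()] or complete genotype matrix (for the MEML
#'   statistic this is typically the prescreened subset).
#' @param A an [a_matrix()].
#' @param statistic `"h2"` (per-SNP heritability from a MEML refit, the
#'   default), `"logp"` (-log10 p from an SMMA refit with its own REML
#'   null fit per permutation), or a function `f(y_perm)` returning the
#'   per-SNP statistic vector.
#' @param n_perm number of permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed; the result is fully reproducible given it.
#' @param config a [meml_config()] for the `"h2"` statistic.
#' @return A `permutation_result`: `null_maxima` (length `n_perm`),
#'   `threshold` (type-7 empirical quantile), `alpha`, `n_perm`, `seed`,
#'   `statistic` label.
#' @export
permutation_threshold <- function(y, panel, A, statistic = "h2",
                                  n_perm = 1000, alpha = 0.05, seed = NULL,
                                  config = meml_config()) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(panel, "snp_panel")) X <- impute_genotypes(panel)
  else X <- as.matrix(panel)
  n <- length(y)
  if (nrow(X) != n) stop("y and panel dimensions disagree")

  stat_fun <- if (is.function(statistic)) {
    statistic
  } else if (identical(statistic, "h2")) {
    e <- a_eigen(A)
    Xtil <- crossprod(e$vectors, X)
    onetil <- drop(crossprod(e$vectors, rep(1, n)))
    p_freq <- (colMeans(X) + 1) / 2
    function(yp) {
      ytil <- drop(crossprod(e$vectors, yp))
      res <- meml_em_cpp(ytil, Xtil, onetil, e$values,
                         config$a, config$b, config$tol, config$max_iter)
      if (isTRUE(res$diverged)) stop("EM diverged in permutation fit")
      snp_heritability(drop(res$gamma), p_freq, stats::var(yp))
    }
  } else if (identical(statistic, "logp")) {
    e <- a_eigen(A)
    Xtil <- crossprod(e$vectors, X)
    onetil <- drop(crossprod(e$vectors, rep(1, n)))
    first_row <- matrix(X[1L, ], nrow(X), ncol(X), byrow = TRUE)
    mono <- colSums(X != first_row) == 0L
    function(yp) {
      ytil <- drop(crossprod(e$vectors, yp))
      vc <- reml_rotated(ytil, onetil, e$values)
      w <- 1 / (vc$sigma_g2 * e$values + vc$sigma_e2)
      p <- gls_scan_rotated(ytil, onetil, Xtil, w)$p
      p[mono] <- NA_real_
      -log10(p)
    }
  } else stop("statistic must be \"h2\", \"logp\" or a function")

  maxima <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ok <- FALSE
    for (try in 1:4) {
      yp <- y[sample.int(n)]
      s <- tryCatch(stat_fun(yp), error = function(e) e)
      if (!inherits(s, "error")) { ok <- TRUE; break }
      if (try == 4) stop("permutation ", b, " failed after 3 retries: ",
                         conditionMessage(s))
    }
    maxima[b] <- max(s, na.rm = TRUE)
  }
  structure(list(null_maxima = maxima,
                 threshold = stats::quantile(maxima, 1 - alpha, type = 7,
                                             names = FALSE),
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 statistic = if (is.function(statistic)) "custom"
                             else statistic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result (", x$statistic, "): threshold = ",
      format(x$threshold, digits = 5), " at alpha = ", x$alpha,
      " from ", x$n_perm, " permutations\n", sep = "")
  invisible(x)
}

#' Write permutation null maxima for audit
#' @param perm a `permutation_result`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_permutation_tsv <- function(perm, path) {
  utils::write.table(
    data.frame(permutation = seq_along(perm$null_maxima),
               max_statistic = perm$null_maxima),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
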