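#' REML fit of the null polygenic model
#'
#' Estimates the variance components of y = mu 1 + g + e with
#' g ~ N(0, sigma_g2 A) and e ~ N(0, sigma_e2 I) by restricted maximum
#' likelihood, using the eigendecomposition of A and a 1-D bounded search
#' over the variance ratio delta = sigma_e2 / sigma_g2 on the log scale in
#' \[1e-5, 1e5\].
#'
#' @param y numeric phenotype vector (length >= 3, non-constant).
#' @param A an [a_matrix()] over the same individuals.
#' @return A `variance_components` list: `sigma_g2`, `sigma_e2`,
#'   `log_likelihood` (restricted), `boundary` (`TRUE` if the ratio hit a
#'   search bound) and `identifiable` (`FALSE` when A is the identity, in
#'   which case only the total variance is determined).
#' @export
fit_null_reml <- function(y, A) {
  n <- length(y)
  if (n < 3) stop("need at least 3 individuals")
  if (anyNA(y)) stop("y must be complete")
  if (stats::var(y) <= 0) stop("phenotype is constant")
  e <- a_eigen(A)
  ytil <- drop(crossprod(e$vectors, y))
  onetil <- drop(crossprod(e$vectors, rep(1, n)))
  r <- reml_rotated(ytil, onetil, e$values)
  sigma_g2 <- r$sigma_g2; sigma_e2 <- r$sigma_e2
  opt <- r$opt
  boundary <- r$boundary; beta <- r$mu
  identifiable <- max(abs(A$values - diag(n))) > 1e-12
  if (!identifiable)
    warning("A is the identity: sigma_g2 and sigma_e2 are not separately ",
            "identifiable (only their sum)")
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 log_likelihood = opt$objective, mu = beta,
                 boundary = boundary, identifiable = identifiable),
            class = "variance_components")
}

# Profile REML on rotated data: y, 1 and the eigenvalues d of A.
# Restricted likelihood at unit sigma_g2 with V = diag(d + delta),
# delta = sigma_e2 / sigma_g2, searched on the log scale in [1e-5, 1e5].
reml_rotated <- function(ytil, onetil, d) {
  n <- length(ytil)
  rll <- function(log_delta) {
    delta <- exp(log_delta)
    v <- d + delta
    w <- 1 / v
    xwx <- sum(onetil^2 * w)
    beta <- sum(onetil * ytil * w) / xwx
    rss <- sum((ytil - beta * onetil)^2 * w)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(xwx) + (n - 1))
  }
  opt <- stats::optimize(rll, interval = log(c(1e-5, 1e5)), maximum = TRUE,
                         tol = 1e-10)
  if (!is.finite(opt$objective)) stop("non-finite REML likelihood")
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  xwx <- sum(onetil^2 * w)
  beta <- sum(onetil * ytil * w) / xwx
  sigma_g2 <- sum((ytil - beta * onetil)^2 * w) / (n - 1)
  list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2, mu = beta,
       opt = opt,
       boundary = opt$maximum <= log(1e-5) + 1e-6 ||
         opt$maximum >= log(1e5) - 1e-6)
}

# Wald scan on rotated data with fixed per-eigenvalue weights w.
gls_scan_rotated <- function(ytil, onetil, Xtil, w) {
  sw <- sum(w * onetil^2)
  swy <- sum(w * onetil * ytil)
  swx <- colSums(Xtil * (w * onetil))
  swxx <- colSums(Xtil^2 * w)
  swxy <- colSums(Xtil * (w * ytil))
  det_ <- sw * swxx - swx^2
  beta <- (sw * swxy - swx * swy) / det_
  se <- sqrt(sw / det_)
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components: sigma_g2 = ", format(x$sigma_g2, digits = 5),
      ", sigma_e2 = ", format(x$sigma_e2, digits = 5),
      ", restricted logLik = ", format(x$log_likelihood, digits = 6),
      if (x$boundary) " [boundary]" else "", "\n", sep = "")
  invisible(x)
}

#' Single-marker mixed-model association scan
#'
#' Per-SNP generalized-least-squares fit of y = mu 1 + x_j gamma_j + eps
#' with Var(eps) = sigma_g2 A + sigma_e2 I held fixed at the null REML
#' estimates (the EMMAX-style approximation), and a two-sided Wald test of
#' gamma_j against the standard normal. Monomorphic SNPs are flagged and
#' get NA statistics.
#'
#' @param y numeric phenotype vector.
#' @param panel a [snp_panel()] (mean-imputed if missing genotypes) or a
#'   complete numeric genotype matrix.
#' @param A an [a_matrix()].
#' @param vc a `variance_components` from [fit_null_reml()] on the same
#'   `y` and `A`; if `NULL` it is fitted here.
#' @return An `smma_result` data.frame with one row per SNP: `snp`,
#'   `chrom`, `pos`, `beta`, `se`, `p`, `tested`; the variance components
#'   are attached as attribute `"vc"`.
#' @export
smma_scan <- function(y, panel, A, vc = NULL) {
  if (inherits(panel, "snp_panel")) {
    X <- impute_genotypes(panel)
    map <- panel$snp_map
  } else {
    X <- as.matrix(panel)
    map <- data.frame(name = colnames(X) %||% paste0("snp", seq_len(ncol(X))),
                      chrom = NA_integer_, pos = seq_len(ncol(X)))
  }
  if (is.null(vc)) vc <- fit_null_reml(y, A)
  e <- a_eigen(A)
  n <- length(y)
  w <- 1 / (vc$sigma_g2 * e$values + vc$sigma_e2)
  ytil <- drop(crossprod(e$vectors, y))
  onetil <- drop(crossprod(e$vectors, rep(1, n)))
  Xtil <- crossprod(e$vectors, X)
  st <- gls_scan_rotated(ytil, onetil, Xtil, w)
  beta <- st$beta; se <- st$se; pval <- st$p

  first_row <- matrix(X[1L, ], nrow(X), ncol(X), byrow = TRUE)
  mono <- colSums(X != first_row) == 0L
  beta[mono] <- NA_real_; se[mono] <- NA_real_; pval[mono] <- NA_real_
  out <- data.frame(snp = map$name, chrom = map$chrom, pos = map$pos,
                    beta = beta, se = se, p = pval, tested = !mono,
                    stringsAsFactors = FALSE)
  attr(out, "vc") <- vc
  class(out) <- c("smma_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the top SNPs of a single-marker scan
#'
#' Returns the (genome-order stable) indices of the `k` smallest p-values;
#' ties at the cutoff are broken toward the earlier genome position.
#' Untested (monomorphic) SNPs are never selected. If `k` exceeds the
#' number of tested SNPs, all tested SNPs are returned with a warning.
#'
#' @param result an `smma_result` from [smma_scan()].
#' @param k number of SNPs to keep (default 500).
#' @return Integer vector of column indices, in genome order.
#' @export
prescreen <- function(result, k = 500) {
  if (k < 1) stop("k must be at least 1")
  idx <- which(result$tested)
  if (k > length(idx)) {
    warning("k = ", k, " exceeds the ", length(idx),
            " tested SNPs; returning all")
    return(idx)
  }
  ord <- idx[order(result$p[idx], seq_along(idx))]   # stable: genome order
  sort(ord[seq_len(k)])
}

#' Write an SMMA result table
#' @param result an `smma_result`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_smma_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
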