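#' Configuration for the MEML fit
#'
#' Hyperparameters and numerical controls of the EM Bayesian-Lasso fit.
#' `a` and `b` are the shape and rate of the Gamma hyperprior on each
#' per-SNP hyperparameter lambda^2_j; both default to 1e-6. The degenerate
#' choice a = b = 0 is rejected: the lambda^2 update has no meaningful
#' limit there.
#'
#' @param a Gamma shape, > 0 (default 1e-6).
#' @param b Gamma rate, > 0 (default 1e-6).
#' @param tol convergence tolerance on the maximum absolute change of
#'   (mu, gamma, sigma_g2, sigma_e2) between iterations (default 1e-8).
#' @param max_iter maximum EM iterations (default 10000).
#' @param seed optional integer seed for any randomized initialization.
#' @return A `meml_config` list.
#' @export
meml_config <- function(a = 1e-6, b = 1e-6, tol = 1e-8, max_iter = 10000,
                        seed = NULL) {
  if (!(a > 0) || !(b > 0))
    stop("a and b must be strictly positive; Gamma(0,0) is not meaningful here")
  if (!(tol > 0) && !is.infinite(tol)) stop("tol must be positive")
  structure(list(a = a, b = b, tol = tol, max_iter = as.integer(max_iter),
                 seed = seed), class = "meml_config")
}

# threshold below which |gamma| is treated as numerically zero in the
# scale E-step, and the consecutive-iteration clamp rule
.gamma_eps <- 1e-12
.clamp_after <- 3L

#' E-step for the polygenic effect
#'
#' Posterior expectation and covariance of the polygenic vector g given the
#' current parameters: with r = y - mu - X gamma,
#' E(g | y) = sigma_g2 A (sigma_g2 A + sigma_e2 I)^-1 r and
#' V(g | y) = sigma_g2 A - sigma_g2 A (sigma_g2 A + sigma_e2 I)^-1 sigma_g2 A.
#' Uses the cached eigendecomposition of A, so each call is O(n^2).
#'
#' @param mu,gamma,sigma_g2,sigma_e2 current parameter values.
#' @param y phenotype vector; `X` complete genotype matrix.
#' @param A an [a_matrix()].
#' @param full_cov if `TRUE` also return the dense posterior covariance
#'   (small-n use only).
#' @return List with `g_hat` and the covariance summaries `tr_Vg`
#'   (trace of V), `tr_Ainv_Vg` (trace of A^-1 V) and `g_Ainv_g`
#'   (g_hat' A^-1 g_hat), plus `Vg` when `full_cov`.
#' @export
e_step_polygenic <- function(mu, gamma, sigma_g2, sigma_e2, y, X, A,
                             full_cov = FALSE) {
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  e <- a_eigen(A)
  d <- e$values
  r <- y - mu - drop(X %*% gamma)
  if (sigma_g2 <= 0) {
    n <- length(y)
    out <- list(g_hat = rep(0, n), tr_Vg = 0, tr_Ainv_Vg = 0, g_Ainv_g = 0)
    if (full_cov) out$Vg <- matrix(0, n, n)
    return(out)
  }
  rtil <- drop(crossprod(e$vectors, r))
  den <- sigma_g2 * d + sigma_e2
  h <- sigma_g2 * d / den
  ghat_til <- h * rtil
  g_hat <- drop(e$vectors %*% ghat_til)
  out <- list(
    g_hat = g_hat,
    tr_Vg = sum(sigma_g2 * d * sigma_e2 / den),
    tr_Ainv_Vg = sum(sigma_g2 * sigma_e2 / den),
    g_Ainv_g = sum(sigma_g2^2 * d * rtil^2 / den^2)
  )
  if (full_cov)
    out$Vg <- e$vectors %*% (t(e$vectors) * (sigma_g2 * d * sigma_e2 / den))
  out
}

#' E-step for the latent per-SNP scales
#'
#' Expectations of 1/tau^2_j and tau^2_j under the conditional density
#' p(tau^2 | gamma, lambda^2), a generalized inverse Gaussian. Closed
#' forms: E(1/tau^2) = sqrt(lambda^2)/|gamma| and
#' E(tau^2) = |gamma|/sqrt(lambda^2) + 1/lambda^2. For |gamma| below
#' 1e-12 the first expectation is capped at sqrt(lambda^2)/1e-12.
#'
#' @param gamma_j SNP effect(s), vectorised.
#' @param lambda2_j positive hyperparameter(s), recycled.
#' @return List with `inv_tau2` and `tau2`.
#' @export
e_step_scales <- function(gamma_j, lambda2_j) {
  if (any(lambda2_j <= 0)) stop("lambda2 must be strictly positive")
  lam <- sqrt(lambda2_j)
  ag <- pmax(abs(gamma_j), .gamma_eps)
  list(inv_tau2 = lam / ag,
       tau2 = abs(gamma_j) / lam + 1 / lambda2_j)
}

#' One M-step of the EM algorithm
#'
#' Conditional maximizers of the expected complete-data log posterior given
#' the E-step expectations, updated in the block order mu, gamma (one
#' coordinate sweep in genome order), lambda^2, sigma_g^2, sigma_e^2.
#'
#' @param y phenotype vector; `X` complete genotype matrix.
#' @param gamma current SNP effects (start of the sweep).
#' @param estep result of [e_step_polygenic()].
#' @param scales result of [e_step_scales()] at the E-step parameters.
#' @param config a [meml_config()].
#' @param clamped logical p-vector: SNPs held at exactly 0 this step.
#' @param update which blocks to update (used by the reference engine to
#'   freeze blocks in validation runs).
#' @return List with `mu`, `gamma`, `lambda2`, `sigma_g2`, `sigma_e2`.
#' @export
m_step <- function(y, X, gamma, estep, scales, config,
                   clamped = rep(FALSE, length(gamma)),
                   update = c("mu", "gamma", "lambda2", "sigma_g2",
                              "sigma_e2"),
                   mu = NULL, lambda2 = NULL, sigma_g2 = NULL,
                   sigma_e2 = NULL) {
  n <- length(y); p <- length(gamma)
  g_hat <- estep$g_hat
  xtx <- colSums(X^2)

  new_mu <- if ("mu" %in% update) mean(y - drop(X %*% gamma) - g_hat)
            else mu
  if (is.null(new_mu)) stop("mu required when not updated")

  new_gamma <- gamma
  if ("gamma" %in% update) {
    rs <- y - new_mu - drop(X %*% new_gamma) - g_hat
    for (j in seq_len(p)) {
      if (clamped[j]) next
      cfull <- sum(X[, j] * rs) + xtx[j] * new_gamma[j]
      gj <- cfull / (xtx[j] + sigma_e2_of(estep, sigma_e2) *
                       scales$inv_tau2[j])
      rs <- rs - X[, j] * (gj - new_gamma[j])
      new_gamma[j] <- gj
    }
  }

  new_lambda2 <- if ("lambda2" %in% update)
    (1 + config$a) / (scales$tau2 / 2 + config$b) else lambda2
  new_sigma_g2 <- if ("sigma_g2" %in% update)
    (estep$g_Ainv_g + estep$tr_Ainv_Vg) / n else sigma_g2
  new_sigma_e2 <- if ("sigma_e2" %in% update) {
    res <- y - new_mu - drop(X %*% new_gamma) - g_hat
    (sum(res^2) + estep$tr_Vg) / (n + 2)
  } else sigma_e2
  list(mu = new_mu, gamma = new_gamma, lambda2 = new_lambda2,
       sigma_g2 = new_sigma_g2, sigma_e2 = new_sigma_e2)
}

# sigma_e2 used inside the gamma sweep: the E-step value (the sweep is a
# conditional maximizer given the E-step expectations, which were formed at
# the old sigma_e2)
sigma_e2_of <- function(estep, fallback) {
  if (!is.null(estep$sigma_e2)) estep$sigma_e2 else fallback
}

#' Observed-data log posterior of the MEML model
#'
#' The objective the EM ascends: the polygenic effect integrated
#' analytically (Gaussian) and the latent scales integrated per SNP, which
#' yields the double-exponential marginal
#' p(gamma_j | lambda_j) = (lambda_j/2) exp(-lambda_j |gamma_j|).
#' The lambda^2 block contributes its Gamma kernel a log(lambda^2) -
#' b lambda^2 (the package's penalised form, under which the pinned
#' lambda^2 update is the exact maximizer), and the residual variance its
#' scale-invariant prior -log(sigma_e2). Additive constants are dropped.
#'
#' @param mu,gamma,lambda2,sigma_g2,sigma_e2 parameter values.
#' @param y,X,A data (A an [a_matrix()]).
#' @param a,b Gamma hyperprior parameters.
#' @return Scalar log posterior (up to an additive constant).
#' @export
meml_log_posterior <- function(mu, gamma, lambda2, sigma_g2, sigma_e2,
                               y, X, A, a = 1e-6, b = 1e-6) {
  e <- a_eigen(A)
  d <- e$values
  r <- y - mu - drop(X %*% gamma)
  rtil <- drop(crossprod(e$vectors, r))
  den <- sigma_g2 * d + sigma_e2
  lam <- sqrt(lambda2)
  -0.5 * sum(log(den)) - 0.5 * sum(rtil^2 / den) +
    sum(0.5 * log(lambda2) - lam * abs(gamma)) +
    sum(a * log(lambda2) - b * lambda2) -
    log(sigma_e2)
}

#' SNP heritability from an effect estimate
#'
#' Fraction of phenotypic variance attributable to one SNP under the
#' \{1,0,-1\} coding and Hardy-Weinberg proportions:
#' h2_j = 2 p_j (1 - p_j) gamma_j^2 / var_y.
#'
#' @param gamma_j additive effect(s).
#' @param p_j reference-allele frequency in \[0, 1\].
#' @param var_y sample phenotypic variance, > 0.
#' @return Heritability value(s).
#' @export
snp_heritability <- function(gamma_j, p_j, var_y) {
  if (any(p_j < 0 | p_j > 1)) stop("allele frequency must be in [0, 1]")
  if (var_y <= 0) stop("var_y must be positive")
  2 * p_j * (1 - p_j) * gamma_j^2 / var_y
}

#' Fit the MEML multi-SNP model
#'
#' Joint maximum-a-posteriori estimation of all SNP effects in
#' y = mu 1 + X gamma + g + e, with g ~ N(0, sigma_g2 A),
#' e ~ N(0, sigma_e2 I), and an independent hierarchical
#' double-exponential (Bayesian Lasso) prior on each gamma_j:
#' gamma_j | tau2_j ~ N(0, tau2_j), tau2_j | lambda2_j ~
#' Exponential(rate lambda2_j / 2), lambda2_j ~ Gamma(a, b). The EM
#' algorithm treats g and the tau2_j as missing data; maximization is over
#' mu, gamma, lambda2, sigma_g2 and sigma_e2.
#'
#' Initialization: mu = mean(y), gamma = 0, lambda2 = 1,
#' sigma_g2 = sigma_e2 = var(y)/2. Iteration stops when the maximum
#' absolute change of (mu, gamma, sigma_g2, sigma_e2) falls below
#' `config$tol`, or after `config$max_iter` iterations.
#'
#' @param y numeric phenotype vector (no missing values).
#' @param panel a [snp_panel()] (missing genotypes are mean-imputed) or a
#'   complete numeric genotype matrix; typically the prescreened subset.
#' @param A an [a_matrix()] over the same individuals, in the same order.
#' @param config a [meml_config()].
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation built from the exported E-step/M-step blocks).
#' @return A `meml_fit` with elements `mu`, `gamma`, `lambda2`, `tau2`
#'   (final E(tau2_j)), `sigma_g2`, `sigma_e2`, `g_hat`, `h2` (per-SNP
#'   heritabilities), `p_freq`, `var_y`, `n_iterations`, `converged`,
#'   `objective_trace` (observed-data log posterior per iteration,
#'   `objective_type = "log_posterior"`), and `snp_map` when the input was
#'   a panel.
#' @export
fit_meml <- function(y, panel, A, config = meml_config(),
                     engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(panel, "snp_panel")) {
    X <- impute_genotypes(panel)
    p_freq <- allele_freq(panel)
    snp_map <- panel$snp_map
  } else {
    X <- as.matrix(panel)
    p_freq <- (colMeans(X) + 1) / 2   # code mean is 2p - 1
    snp_map <- NULL
  }
  if (length(y) != nrow(X)) stop("y and panel dimensions disagree")
  if (anyNA(y)) stop("y must be complete")
  if (stats::var(y) <= 0) stop("phenotype is constant")
  e <- a_eigen(A)
  Xtil <- crossprod(e$vectors, X)
  ytil <- drop(crossprod(e$vectors, y))
  onetil <- drop(crossprod(e$vectors, rep(1, length(y))))
  res <- if (engine == "cpp") {
    out <- meml_em_cpp(ytil, Xtil, onetil, e$values,
                       config$a, config$b, config$tol, config$max_iter)
    out$g_hat <- drop(e$vectors %*% out$ghat_til)
    out
  } else {
    meml_em_r(y, X, A, config)
  }
  if (isTRUE(res$diverged)) {
    err <- simpleError(paste0("EM diverged at iteration ", res$n_iterations,
                              ": objective decreased by more than 1e-6"))
    err$state <- res
    stop(err)
  }
  var_y <- stats::var(y)
  fit <- structure(list(
    mu = res$mu, gamma = drop(res$gamma), lambda2 = drop(res$lambda2),
    tau2 = e_step_scales(drop(res$gamma), drop(res$lambda2))$tau2,
    sigma_g2 = res$sigma_g2, sigma_e2 = res$sigma_e2,
    g_hat = drop(res$g_hat),
    h2 = snp_heritability(drop(res$gamma), p_freq, var_y),
    p_freq = p_freq, var_y = var_y,
    n_iterations = res$n_iterations, converged = res$converged,
    objective_trace = drop(res$objective_trace),
    objective_type = "log_posterior",
    snp_map = snp_map, config = config, engine = engine
  ), class = "meml_fit")
  fit
}

#' @export
print.meml_fit <- function(x, ...) {
  cat("meml_fit: ", length(x$gamma), " SNPs, n_iter = ", x$n_iterations,
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      "  sigma_g2 = ", format(x$sigma_g2, digits = 4),
      ", sigma_e2 = ", format(x$sigma_e2, digits = 4), "\n",
      "  max h2 = ", format(max(x$h2), digits = 4),
      ", non-zero effects (|gamma| > 1e-6): ", sum(abs(x$gamma) > 1e-6),
      "\n", sep = "")
  invisible(x)
}

# Pure-R reference engine: the exact loop the compiled engine implements,
# built from the exported blocks. Supports freezing parameter blocks.
meml_em_r <- function(y, X, A, config,
                      update = c("mu", "gamma", "lambda2", "sigma_g2",
                                 "sigma_e2"),
                      init = NULL) {
  n <- length(y); p <- ncol(X)
  mu <- mean(y); gamma <- rep(0, p); lambda2 <- rep(1, p)
  sigma_g2 <- sigma_e2 <- stats::var(y) / 2
  if (!is.null(init))
    for (nm in names(init)) assign(nm, init[[nm]])
  below <- integer(p); clamped <- rep(FALSE, p)
  obj <- numeric(0)
  converged <- FALSE; diverged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    estep <- e_step_polygenic(mu, gamma, sigma_g2, sigma_e2, y, X, A)
    estep$sigma_e2 <- sigma_e2
    scales <- e_step_scales(gamma, lambda2)
    # re-entry: a clamped SNP whose partial-residual correlation is the
    # sweep's largest is released
    r0 <- y - mu - drop(X %*% gamma) - estep$g_hat
    score <- abs(drop(crossprod(X, r0)) + colSums(X^2) * gamma)
    jmax <- which.max(score)
    if (clamped[jmax]) { clamped[jmax] <- FALSE; below[jmax] <- 0L }
    upd <- m_step(y, X, gamma, estep, scales, config, clamped = clamped,
                  update = update, mu = mu, lambda2 = lambda2,
                  sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)
    delta <- max(abs(upd$mu - mu), max(abs(upd$gamma - gamma)),
                 abs(upd$sigma_g2 - sigma_g2), abs(upd$sigma_e2 - sigma_e2))
    mu <- upd$mu; gamma <- upd$gamma; lambda2 <- upd$lambda2
    sigma_g2 <- upd$sigma_g2; sigma_e2 <- upd$sigma_e2
    tiny <- abs(gamma) < .gamma_eps & !clamped
    below[tiny] <- below[tiny] + 1L
    below[!tiny & !clamped] <- 0L
    newly <- below >= .clamp_after & !clamped
    clamped[newly] <- TRUE
    gamma[clamped] <- 0
    obj <- c(obj, meml_log_posterior(mu, gamma, lambda2, sigma_g2, sigma_e2,
                                     y, X, A, config$a, config$b))
    k <- length(obj)
    if (k >= 2 && obj[k] < obj[k - 1] - 1e-6) { diverged <- TRUE; break }
    if (delta < config$tol) { converged <- is.finite(config$tol); break }
  }
  list(mu = mu, gamma = gamma, lambda2 = lambda2, sigma_g2 = sigma_g2,
       sigma_e2 = sigma_e2, g_hat = e_step_polygenic(
         mu, gamma, sigma_g2, sigma_e2, y, X, A)$g_hat,
       n_iterations = it, converged = converged, diverged = diverged,
       objective_trace = obj)
}
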