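# Independent numeric oracles used to validate the analytic updates.
# These deliberately avoid the package's own closed forms: quadrature for
# the latent-scale expectations, dense linear algebra for the polygenic
# posterior, 1-D golden-section/grid argmax for the M-step blocks, and the
# Henderson T D T' decomposition for the relationship matrix.

# conditional density of tau2 given (gamma, lambda2), unnormalised
gig_moment <- function(fun, gamma, lambda2) {
  dens <- function(t) t^(-0.5) * exp(-gamma^2 / (2 * t) - lambda2 * t / 2)
  num <- stats::integrate(function(t) fun(t) * dens(t), 0, Inf,
                          rel.tol = 1e-10, abs.tol = 0)$value
  den <- stats::integrate(dens, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  num / den
}

# expected complete-data log posterior (Q-function) given E-step
# expectations, up to additive constants; the independent reference for
# the M-step argmax checks
q_function <- function(mu, gamma, lambda2, sigma_g2, sigma_e2,
                       y, X, estep, scales, a, b) {
  n <- length(y)
  res <- y - mu - drop(X %*% gamma) - estep$g_hat
  e_rss <- sum(res^2) + estep$tr_Vg
  e_gag <- estep$g_Ainv_g + estep$tr_Ainv_Vg
  -0.5 * n * log(sigma_e2) - e_rss / (2 * sigma_e2) -
    log(sigma_e2) +
    (if (sigma_g2 > 0) -0.5 * n * log(sigma_g2) - e_gag / (2 * sigma_g2)
     else -Inf) -
    0.5 * sum(scales$inv_tau2 * gamma^2) +
    sum(log(lambda2) - lambda2 * scales$tau2 / 2) +
    sum(a * log(lambda2) - b * lambda2)
}

# 1-D numeric argmax by coarse grid + optimize refinement
argmax_1d <- function(f, lower, upper, n_grid = 400) {
  xs <- seq(lower, upper, length.out = n_grid)
  vs <- vapply(xs, f, 0)
  i <- which.max(vs)
  lo <- xs[max(1, i - 1)]; hi <- xs[min(n_grid, i + 1)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
}

# Henderson decomposition A = T D T': an implementation independent of the
# tabular recursion (T built column-wise from parent averages, D from
# parental inbreeding coefficients)
a_matrix_henderson <- function(ped) {
  n <- length(ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  T <- diag(n)
  for (i in seq_len(n)) {
    if (!is.na(si[i])) T[i, ] <- T[i, ] + 0.5 * T[si[i], ]
    if (!is.na(di[i])) T[i, ] <- T[i, ] + 0.5 * T[di[i], ]
    T[i, i] <- 1
  }
  # inbreeding coefficients from the recursively built A itself would be
  # circular; compute F from T D T' progressively instead
  D <- numeric(n)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Fs <- if (!is.na(si[i])) A[si[i], si[i]] - 1 else NA
    Fd <- if (!is.na(di[i])) A[di[i], di[i]] - 1 else NA
    D[i] <- if (!is.na(si[i]) && !is.na(di[i])) 0.5 - 0.25 * (Fs + Fd)
            else if (!is.na(si[i])) 0.75 - 0.25 * Fs
            else if (!is.na(di[i])) 0.75 - 0.25 * Fd
            else 1
    Ti <- T[seq_len(i), seq_len(i), drop = FALSE]
    A[seq_len(i), seq_len(i)] <-
      Ti %*% diag(D[seq_len(i)], i) %*% t(Ti)
  }
  A
}
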