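test_that("latent-scale expectations match adaptive quadrature of the GIG", {
  # worked value: gamma = 1, lambda2 = 4 -> E[1/tau2] = 2
  es <- e_step_scales(1, 4)
  expect_equal(es$inv_tau2, 2, tolerance = 1e-10)
  cases <- expand.grid(gamma = c(0.05, 0.3, 1, 2.7),
                       lambda2 = c(0.25, 1, 4, 30))
  for (i in seq_len(nrow(cases))) {
    g <- cases$gamma[i]; l2 <- cases$lambda2[i]
    es <- e_step_scales(g, l2)
    expect_equal(es$inv_tau2, gig_moment(function(t) 1 / t, g, l2),
                 tolerance = 1e-6)
    expect_equal(es$tau2, gig_moment(function(t) t, g, l2),
                 tolerance = 1e-6)
    # sign symmetry
    esn <- e_step_scales(-g, l2)
    expect_identical(es, esn)
  }
  # |gamma| -> infinity sends E[1/tau2] to 0; tiny gamma hits the cap
  expect_lt(e_step_scales(1e6, 1)$inv_tau2, 1e-5)
  expect_equal(e_step_scales(0, 4)$inv_tau2, 2 / 1e-12)
  expect_error(e_step_scales(1, 0), "positive")
})

test_that("polygenic E-step matches a dense-solve oracle", {
  inst <- small_instance(n = 8, p = 2, seed = 3, beta = c(0.5, 0))
  mu <- 0.8; gamma <- c(0.3, -0.2); sg <- 0.7; se <- 1.3
  es <- e_step_polygenic(mu, gamma, sg, se, inst$y, inst$X, inst$A,
                         full_cov = TRUE)
  Av <- inst$A$values
  r <- inst$y - mu - inst$X %*% gamma
  M <- solve(sg * Av + se * diag(8))
  g_dense <- drop(sg * Av %*% M %*% r)
  V_dense <- sg * Av - sg * Av %*% M %*% (sg * Av)
  expect_equal(es$g_hat, unname(g_dense), tolerance = 1e-10)
  expect_equal(es$Vg, unname(V_dense), tolerance = 1e-10)
  expect_equal(es$tr_Vg, sum(diag(V_dense)), tolerance = 1e-10)
  expect_equal(es$tr_Ainv_Vg, sum(diag(solve(Av) %*% V_dense)),
               tolerance = 1e-8)
  expect_equal(es$g_Ainv_g, drop(g_dense %*% solve(Av) %*% g_dense),
               tolerance = 1e-8)
  # limits: sigma_g2 -> 0 and sigma_e2 -> 0 with A = I
  es0 <- e_step_polygenic(mu, gamma, 0, se, inst$y, inst$X, inst$A)
  expect_equal(es0$g_hat, rep(0, 8))
  AI <- as_a_matrix(diag(8))
  esr <- e_step_polygenic(mu, gamma, 1, 1e-12, inst$y, inst$X, AI)
  expect_equal(esr$g_hat, drop(r), tolerance = 1e-6)
})

test_that("every M-step block matches its numeric argmax oracle", {
  for (seed in c(2, 7, 19)) {
    inst <- small_instance(n = 12, p = 3, seed = seed,
                           beta = c(0.6, 0, -0.4))
    y <- inst$y; X <- inst$X
    mu <- mean(y); gamma <- c(0.2, -0.1, 0.05)
    lambda2 <- c(1, 2, 0.5); sg <- 0.4; se <- 0.9
    cfg <- meml_config()
    estep <- e_step_polygenic(mu, gamma, sg, se, y, X, inst$A)
    scales <- e_step_scales(gamma, lambda2)
    upd <- m_step(y, X, gamma, estep, scales, cfg, mu = mu,
                  lambda2 = lambda2, sigma_g2 = sg, sigma_e2 = se)

    qf <- function(mu_, gamma_, lambda2_, sg_, se_)
      q_function(mu_, gamma_, lambda2_, sg_, se_, y, X, estep, scales,
                 cfg$a, cfg$b)

    # mu block (gamma still at its pre-sweep value)
    mu_star <- argmax_1d(function(m) qf(m, gamma, lambda2, sg, se), -5, 5)
    expect_equal(upd$mu, mu_star, tolerance = 1e-6)

    # gamma sweep, coordinate by coordinate in genome order; the sweep
    # residual uses the updated mu and previously updated coordinates,
    # and the E-step sigma_e2 in the penalty
    gam <- gamma
    for (j in 1:3) {
      gam_j <- argmax_1d(function(g) {
        gg <- gam; gg[j] <- g
        qf(upd$mu, gg, lambda2, sg, se)
      }, -3, 3)
      gam[j] <- gam_j
    }
    expect_equal(upd$gamma, gam, tolerance = 1e-6)

    # lambda2 block
    for (j in 1:3) {
      l_star <- argmax_1d(function(l) {
        ll <- lambda2; ll[j] <- l
        qf(upd$mu, upd$gamma, ll, sg, se)
      }, 1e-4, 50)
      expect_equal(upd$lambda2[j], l_star, tolerance = 1e-6)
    }

    # variance blocks
    sg_star <- argmax_1d(function(s) qf(upd$mu, upd$gamma, lambda2, s, se),
                         1e-4, 5)
    expect_equal(upd$sigma_g2, sg_star, tolerance = 1e-6)
    se_star <- argmax_1d(function(s) {
      res <- y - upd$mu - drop(X %*% upd$gamma) - estep$g_hat
      -0.5 * length(y) * log(s) - (sum(res^2) + estep$tr_Vg) / (2 * s) -
        log(s)
    }, 1e-4, 5)
    expect_equal(upd$sigma_e2, se_star, tolerance = 1e-6)
  }
})

test_that("the lambda2 update degenerates gracefully only at a = b = 0", {
  # at a = b = 1e-6 and E[tau2] = 2 the update is about 1
  cfg <- meml_config()
  scales <- list(tau2 = 2, inv_tau2 = 1)
  lam2 <- (1 + cfg$a) / (scales$tau2 / 2 + cfg$b)
  expect_equal(lam2, 1, tolerance = 1e-5)
  expect_error(meml_config(a = 0, b = 0), "Gamma")
})

test_that("a penalty-free sweep on orthonormal X reproduces least squares", {
  set.seed(8)
  n <- 16
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  y <- rnorm(n)
  estep <- list(g_hat = rep(0, n), tr_Vg = 0, tr_Ainv_Vg = 0, g_Ainv_g = 0,
                sigma_e2 = 1)
  scales <- list(inv_tau2 = rep(0, 3), tau2 = rep(1, 3))
  upd <- m_step(y, Q, rep(0, 3), estep, scales, meml_config(),
                update = "gamma", mu = 0, lambda2 = rep(1, 3),
                sigma_g2 = 0, sigma_e2 = 1)
  ls <- lm(y ~ Q - 1)
  expect_equal(upd$gamma, unname(coef(ls)), tolerance = 1e-8)
})

test_that("EM ascends the observed-data log posterior on small instances", {
  for (seed in 1:20) {
    beta <- if (seed %% 2) c(0.8, 0) else c(0, 0)
    inst <- small_instance(n = 15, p = 2, seed = 400 + seed, beta = beta)
    fit <- fit_meml(inst$y, inst$X, inst$A,
                    config = meml_config(max_iter = 400), engine = "r")
    expect_gt(min(diff(fit$objective_trace)), -1e-8)
  }
})

test_that("the trace reports the same posterior the closed form computes", {
  inst <- small_instance(n = 15, p = 2, seed = 99, beta = c(0.7, 0))
  fit <- fit_meml(inst$y, inst$X, inst$A,
                  config = meml_config(max_iter = 50), engine = "r")
  lp <- meml_log_posterior(fit$mu, fit$gamma, fit$lambda2, fit$sigma_g2,
                           fit$sigma_e2, inst$y, inst$X, inst$A)
  expect_equal(lp, fit$objective_trace[length(fit$objective_trace)],
               tolerance = 1e-8)
  # the double-exponential marginal used in it equals the quadrature of
  # the normal-exponential mixture over tau2
  for (g in c(0.3, 1.2)) {
    lam2 <- 2.5
    de_closed <- sqrt(lam2) / 2 * exp(-sqrt(lam2) * abs(g))
    de_quad <- stats::integrate(function(t)
      stats::dnorm(g, 0, sqrt(t)) * lam2 / 2 * exp(-lam2 * t / 2),
      0, Inf, rel.tol = 1e-10)$value
    expect_equal(de_closed, de_quad, tolerance = 1e-8)
  }
})

test_that("compiled and reference engines agree", {
  inst <- small_instance(n = 30, p = 8, seed = 55,
                         beta = c(1, rep(0, 7)))
  f1 <- fit_meml(inst$y, inst$X, inst$A)
  f2 <- fit_meml(inst$y, inst$X, inst$A, engine = "r")
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-8)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-10)
  expect_equal(f1$sigma_g2, f2$sigma_g2, tolerance = 1e-10)
  expect_equal(f1$sigma_e2, f2$sigma_e2, tolerance = 1e-10)
  expect_equal(f1$n_iterations, f2$n_iterations)
  expect_equal(f1$objective_trace, f2$objective_trace, tolerance = 1e-8)
})

test_that("EM fixed point matches a grid-search MAP with variances fixed", {
  for (seed in c(5, 17)) {
    inst <- small_instance(n = 20, p = 2, seed = seed, beta = c(1.2, -0.8),
                           sigma_g2 = 0.3, sigma_e2 = 0.8)
    y <- inst$y; X <- inst$X; Av <- inst$A$values
    sg <- 0.3; se <- 0.8; lam2 <- c(4, 4)
    res <- memlgwas:::meml_em_r(y, X, inst$A,
                                meml_config(max_iter = 5000, tol = 1e-12),
                                update = "gamma",
                                init = list(mu = 0, lambda2 = lam2,
                                            sigma_g2 = sg, sigma_e2 = se))
    # independent MAP: profile the marginal posterior (g integrated
    # analytically, tau2 integrated to the double-exponential) on a grid
    V <- sg * Av + se * diag(20)
    Vi <- solve(V)
    lpost <- function(g1, g2) {
      r <- y - X %*% c(g1, g2)
      -0.5 * drop(t(r) %*% Vi %*% r) - sqrt(lam2[1]) * abs(g1) -
        sqrt(lam2[2]) * abs(g2)
    }
    gr <- seq(-2, 2, length.out = 161)
    vals <- outer(gr, gr, Vectorize(lpost))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    g_start <- c(gr[ij[1]], gr[ij[2]])
    ref <- optim(g_start, function(g) -lpost(g[1], g[2]),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$par
    expect_equal(res$gamma, ref, tolerance = 1e-4)
  }
})

test_that("null data are shrunk to zero and a strong QTL is recovered", {
  # pure noise: every effect collapses
  set.seed(321)
  ped <- rand_pedigree(200, n_founders = 60, seed = 321)
  A <- a_matrix(ped)
  X <- matrix(sample(c(1, 0, -1), 200 * 50, TRUE, c(.25, .5, .25)), 200, 50)
  y <- rnorm(200)
  fit <- fit_meml(y, X, A)
  expect_true(all(abs(fit$gamma) < 1e-4))
  expect_true(all(fit$h2 < 1e-6))

  # one QTL at ~20% of variance, n = 500: recovered as the maximum
  set.seed(654)
  ped2 <- rand_pedigree(500, n_founders = 120, seed = 654)
  A2 <- a_matrix(ped2)
  X2 <- matrix(sample(c(1, 0, -1), 500 * 30, TRUE, c(.25, .5, .25)), 500, 30)
  beta <- sqrt(0.25 / 0.5)
  e2 <- a_eigen(A2)
  y2 <- drop(X2[, 7] * beta) +
    drop(e2$vectors %*% (sqrt(e2$values) * rnorm(500))) * sqrt(0.15) +
    rnorm(500, 0, sqrt(0.85))
  fit2 <- fit_meml(y2, X2, A2)
  expect_equal(which.max(fit2$h2), 7L)
  expect_lt(abs(fit2$h2[7] - 0.2), 0.08)
})

test_that("scale equivariance: c * y scales gamma and leaves h2 unchanged", {
  inst <- small_instance(n = 60, p = 5, seed = 77, beta = c(1, 0, 0, 0, 0))
  f1 <- fit_meml(inst$y, inst$X, inst$A)
  f2 <- fit_meml(3 * inst$y, inst$X, inst$A)
  expect_equal(f2$gamma, 3 * f1$gamma, tolerance = 1e-6)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-8)
})

test_that("configuration guards and trivial contracts hold", {
  inst <- small_instance(n = 10, p = 2, seed = 1)
  fit <- fit_meml(inst$y, inst$X, inst$A, config = meml_config(tol = Inf))
  expect_equal(fit$n_iterations, 1L)
  expect_false(fit$converged)
  expect_error(fit_meml(rep(1, 10), inst$X, inst$A), "constant")
  expect_error(meml_config(a = -1), "positive")

  expect_equal(snp_heritability(0, 0.4, 2), 0)
  expect_equal(snp_heritability(1.5, 1, 2), 0)
  expect_equal(snp_heritability(1, 0.5, 4), 0.125)
  expect_error(snp_heritability(1, 0.5, 0), "positive")
  expect_error(snp_heritability(1, 1.4, 1), "frequency")
})
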