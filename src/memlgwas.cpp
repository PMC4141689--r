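// Compiled kernels: tabular relationship matrix, the MEML EM loop, and
// gamete formation for the gene-dropping simulator.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tabular (recursive) numerator relationship matrix. si/di are 1-based
// parent indices into the topologically sorted pedigree, NA_INTEGER for an
// unknown parent; every parent index is smaller than its offspring's.
// [[Rcpp::export]]
NumericMatrix a_matrix_tabular_cpp(IntegerVector si, IntegerVector di) {
  const int n = si.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = si[i] == NA_INTEGER ? -1 : si[i] - 1;
    const int d = di[i] == NA_INTEGER ? -1 : di[i] - 1;
    if (s >= i || d >= i) stop("pedigree is not topologically sorted");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = v;
      A(j, i) = v;
    }
    A(i, i) = 1.0 + (s >= 0 && d >= 0 ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

static const double GAMMA_EPS = 1e-12;
static const int CLAMP_AFTER = 3;

// EM loop for the MEML model, entirely in the eigenbasis of A: with
// A = U diag(d) U', the inputs are ytil = U'y, Xtil = U'X, onetil = U'1.
// Inner products are rotation-invariant, so every E- and M-step quantity
// is available at O(n p) per iteration with no dense n x n product.
// Mirrors the pure-R reference engine exactly. Returns ghat_til (the
// rotated polygenic expectation); the caller maps it back with U.
// [[Rcpp::export]]
List meml_em_cpp(const arma::vec& ytil, const arma::mat& Xtil,
                 const arma::vec& onetil, const arma::vec& d,
                 double a, double b, double tol, int max_iter) {
  const int n = ytil.n_elem, p = Xtil.n_cols;
  const arma::vec xtx = arma::sum(arma::square(Xtil), 0).t();
  const double sum_y = arma::dot(onetil, ytil);

  // mean and variance of y are rotation-invariant functions of ytil
  double mu = sum_y / n;
  double vy = (arma::dot(ytil, ytil) - n * mu * mu) / (n - 1);
  arma::vec gamma(p, arma::fill::zeros);
  arma::vec lambda2(p, arma::fill::ones);
  double sigma_g2 = vy / 2.0, sigma_e2 = vy / 2.0;

  arma::ivec below(p, arma::fill::zeros);
  std::vector<bool> clamped(p, false);
  std::vector<double> obj;
  obj.reserve(256);
  bool converged = false, diverged = false;
  int it = 0;

  arma::vec rtil(n), den(n), ghat_til(n, arma::fill::zeros);
  arma::vec inv_tau2(p), tau2(p);

  // X gamma accumulated over the non-zero coordinates only: after the
  // clamp rule takes hold most of gamma is exactly zero, and skipping
  // exact-zero terms changes nothing in the sum
  arma::vec xg(n);
  auto accum_xg = [&]() {
    xg.zeros();
    for (int j = 0; j < p; ++j)
      if (gamma[j] != 0.0) xg += Xtil.col(j) * gamma[j];
  };

  accum_xg();
  while (it < max_iter) {
    ++it;
    // E-step: polygenic effect (rotated space); xg is current here
    // (recomputed after the sweep at the end of each iteration)
    rtil = ytil - mu * onetil - xg;
    den = sigma_g2 * d + sigma_e2;
    double tr_Vg = 0.0, tr_Ainv_Vg = 0.0, g_Ainv_g = 0.0;
    if (sigma_g2 > 0) {
      ghat_til = (sigma_g2 * d) % rtil / den;
      for (int i = 0; i < n; ++i) {
        tr_Vg += sigma_g2 * d[i] * sigma_e2 / den[i];
        tr_Ainv_Vg += sigma_g2 * sigma_e2 / den[i];
        g_Ainv_g += sigma_g2 * sigma_g2 * d[i] * rtil[i] * rtil[i]
                    / (den[i] * den[i]);
      }
    } else {
      ghat_til.zeros();
    }
    // E-step: latent scales
    for (int j = 0; j < p; ++j) {
      double lam = std::sqrt(lambda2[j]);
      double ag = std::fabs(gamma[j]);
      inv_tau2[j] = lam / std::max(ag, GAMMA_EPS);
      tau2[j] = ag / lam + 1.0 / lambda2[j];
    }

    // re-entry: release the clamped SNP with the sweep's largest
    // partial-residual correlation
    arma::vec r0til = rtil - ghat_til;
    arma::vec score = arma::abs(Xtil.t() * r0til + xtx % gamma);
    arma::uword jmax = score.index_max();
    if (clamped[jmax]) { clamped[jmax] = false; below[jmax] = 0; }

    // M-step
    double mu_new = (sum_y - arma::dot(onetil, xg) -
                     arma::dot(onetil, ghat_til)) / n;
    arma::vec rstil = ytil - mu_new * onetil - xg - ghat_til;
    double max_dgamma = 0.0;
    for (int j = 0; j < p; ++j) {
      if (clamped[j]) continue;
      double cfull = arma::dot(Xtil.col(j), rstil) + xtx[j] * gamma[j];
      double gj = cfull / (xtx[j] + sigma_e2 * inv_tau2[j]);
      double diff = gj - gamma[j];
      if (std::fabs(diff) > max_dgamma) max_dgamma = std::fabs(diff);
      if (diff != 0.0) rstil -= Xtil.col(j) * diff;
      gamma[j] = gj;
    }
    for (int j = 0; j < p; ++j)
      lambda2[j] = (1.0 + a) / (tau2[j] / 2.0 + b);
    double sigma_g2_new = (g_Ainv_g + tr_Ainv_Vg) / n;
    double sigma_e2_new = (arma::dot(rstil, rstil) + tr_Vg) / (n + 2.0);

    double delta = std::max(std::fabs(mu_new - mu), max_dgamma);
    delta = std::max(delta, std::fabs(sigma_g2_new - sigma_g2));
    delta = std::max(delta, std::fabs(sigma_e2_new - sigma_e2));
    mu = mu_new; sigma_g2 = sigma_g2_new; sigma_e2 = sigma_e2_new;

    // clamp rule: |gamma| < 1e-12 for 3 consecutive iterations -> exact 0
    for (int j = 0; j < p; ++j) {
      if (clamped[j]) { gamma[j] = 0.0; continue; }
      if (std::fabs(gamma[j]) < GAMMA_EPS) {
        if (++below[j] >= CLAMP_AFTER) { clamped[j] = true; gamma[j] = 0.0; }
      } else {
        below[j] = 0;
      }
    }

    // observed-data log posterior (additive constants dropped)
    accum_xg();
    rtil = ytil - mu * onetil - xg;
    den = sigma_g2 * d + sigma_e2;
    double lp = -std::log(sigma_e2);
    for (int i = 0; i < n; ++i)
      lp += -0.5 * std::log(den[i]) - 0.5 * rtil[i] * rtil[i] / den[i];
    for (int j = 0; j < p; ++j)
      lp += 0.5 * std::log(lambda2[j]) -
            std::sqrt(lambda2[j]) * std::fabs(gamma[j]) +
            a * std::log(lambda2[j]) - b * lambda2[j];
    obj.push_back(lp);
    size_t k = obj.size();
    if (k >= 2 && obj[k - 1] < obj[k - 2] - 1e-6) { diverged = true; break; }
    if (delta < tol) { converged = std::isfinite(tol); break; }
  }

  if (sigma_g2 > 0) {
    accum_xg();
    rtil = ytil - mu * onetil - xg;
    ghat_til = (sigma_g2 * d) % rtil / (sigma_g2 * d + sigma_e2);
  } else {
    ghat_til.zeros();
  }
  return List::create(
    _["mu"] = mu, _["gamma"] = gamma, _["lambda2"] = lambda2,
    _["sigma_g2"] = sigma_g2, _["sigma_e2"] = sigma_e2,
    _["ghat_til"] = ghat_til, _["n_iterations"] = it,
    _["converged"] = converged, _["diverged"] = diverged,
    _["objective_trace"] = obj);
}

// Gametes by meiosis with recombination: crossover count ~ Poisson(map
// length in Morgans), breakpoints uniform, no interference (Haldane).
// haps: (2N x L) 0/1 haplotypes, rows 2k-1, 2k belong to individual k.
// parent: 1-based individual indices, one gamete per entry.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix make_gametes_cpp(const IntegerMatrix& haps,
                               const IntegerVector& parent,
                               const NumericVector& pos, double chrom_len) {
  const int L = haps.ncol(), m = parent.size();
  IntegerMatrix out(m, L);
  for (int k = 0; k < m; ++k) {
    const int r1 = 2 * (parent[k] - 1), r2 = r1 + 1;
    int nx = (int) R::rpois(chrom_len);
    std::vector<double> bp(nx);
    for (int c = 0; c < nx; ++c) bp[c] = R::runif(0.0, chrom_len);
    std::sort(bp.begin(), bp.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int ci = 0;
    for (int l = 0; l < L; ++l) {
      while (ci < nx && bp[ci] <= pos[l]) { cur = 1 - cur; ++ci; }
      out(k, l) = cur == 0 ? haps(r1, l) : haps(r2, l);
    }
  }
  return out;
}
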