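#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the four-class normal-mixture Bayesian regression
// (Bayes R). Effects a_j have prior N(0, gamma_k * sigma2_a) for mixture
// class k (gamma_1 = 0 is a point mass at zero). Mixture proportions get a
// Dirichlet(1,1,1,1) prior, the residual variance a scaled inverse
// chi-square, and the class-variance scale sigma2_a is re-sampled each sweep
// from its scaled-inverse-chi-square conditional given the current effects.
// Fixed effects (intercept, breed, ...) have flat priors and are sampled by
// single-site Gibbs. All randomness comes from R's RNG, so set.seed() in R
// makes the run deterministic.

// [[Rcpp::export]]
List bayes_r_gibbs(NumericMatrix X, NumericVector y, NumericMatrix F,
                   NumericVector gamma, int iterations, int burn_in,
                   int thin, double nu0, double s_e0, double s_a0) {
  const int n = X.nrow(), m = X.ncol(), q = F.ncol(), K = gamma.size();
  RNGScope scope;

  std::vector<double> xx(m), ff(q);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }
  for (int k = 0; k < q; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += F(i, k) * F(i, k);
    ff[k] = s;
  }

  std::vector<double> a(m, 0.0), b(q, 0.0), e(y.begin(), y.end());
  std::vector<int> cls(m, 0);
  double vary = Rcpp::var(y);
  double sigma2_e = 0.5 * vary, sigma2_a = 0.5 * vary;
  NumericVector pi(K, 1.0 / K);

  NumericVector a_mean(m, 0.0);
  NumericMatrix cls_prob(m, K);
  NumericVector pi_mean(K, 0.0), b_mean(q, 0.0);
  double s2e_mean = 0.0, s2a_mean = 0.0, s2g_mean = 0.0;
  int n_keep = 0;

  std::vector<double> logl(K), vk(K);

  for (int it = 0; it < iterations; ++it) {
    // fixed effects: flat prior, single-site Gibbs
    for (int k = 0; k < q; ++k) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += F(i, k) * e[i];
      rhs += ff[k] * b[k];
      double mean = rhs / ff[k];
      double bnew = R::rnorm(mean, std::sqrt(sigma2_e / ff[k]));
      double diff = bnew - b[k];
      for (int i = 0; i < n; ++i) e[i] -= F(i, k) * diff;
      b[k] = bnew;
    }

    // variant effects: class then effect
    IntegerVector counts(K);
    for (int j = 0; j < m; ++j) {
      const double aj = a[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xx[j] * aj;  // e currently excludes nothing; add back own term

      double lmax = R_NegInf;
      for (int k = 0; k < K; ++k) {
        vk[k] = gamma[k] * sigma2_a;
        if (vk[k] <= 0.0) {
          logl[k] = std::log(pi[k] + 1e-300);
        } else {
          double c = xx[j] * vk[k] + sigma2_e;
          logl[k] = std::log(pi[k] + 1e-300)
            + 0.5 * std::log(sigma2_e / c)
            + 0.5 * rhs * rhs * vk[k] / (sigma2_e * c);
        }
        if (logl[k] > lmax) lmax = logl[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { logl[k] = std::exp(logl[k] - lmax); tot += logl[k]; }
      double u = R::runif(0.0, 1.0) * tot, acc = 0.0;
      int knew = K - 1;
      for (int k = 0; k < K; ++k) { acc += logl[k]; if (u <= acc) { knew = k; break; } }

      double anew = 0.0;
      if (gamma[knew] > 0.0) {
        double C = xx[j] + sigma2_e / vk[knew];
        anew = R::rnorm(rhs / C, std::sqrt(sigma2_e / C));
      }
      double diff = anew - aj;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
      a[j] = anew;
      cls[j] = knew;
      counts[knew]++;
    }

    // mixture proportions ~ Dirichlet(1 + counts)
    double dsum = 0.0;
    for (int k = 0; k < K; ++k) { pi[k] = R::rgamma(1.0 + counts[k], 1.0); dsum += pi[k]; }
    for (int k = 0; k < K; ++k) pi[k] /= dsum;

    // residual variance ~ scaled inverse chi-square
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = (sse + nu0 * s_e0) / R::rchisq(n + nu0);

    // class-variance scale ~ scaled inverse chi-square given effects
    double ssa = 0.0; int m_nz = 0;
    for (int j = 0; j < m; ++j)
      if (gamma[cls[j]] > 0.0) { ssa += a[j] * a[j] / gamma[cls[j]]; ++m_nz; }
    sigma2_a = (ssa + nu0 * s_a0) / R::rchisq(m_nz + nu0);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_keep;
      double gsum = 0.0, gsq = 0.0;
      for (int i = 0; i < n; ++i) {
        double fi = 0.0;
        for (int k = 0; k < q; ++k) fi += F(i, k) * b[k];
        double gi = y[i] - fi - e[i];
        gsum += gi; gsq += gi * gi;
      }
      double gvar = (gsq - gsum * gsum / n) / (n - 1);
      s2g_mean += gvar;
      s2e_mean += sigma2_e;
      s2a_mean += sigma2_a;
      for (int j = 0; j < m; ++j) { a_mean[j] += a[j]; cls_prob(j, cls[j]) += 1.0; }
      for (int k = 0; k < K; ++k) pi_mean[k] += pi[k];
      for (int k = 0; k < q; ++k) b_mean[k] += b[k];
    }
  }

  for (int j = 0; j < m; ++j) {
    a_mean[j] /= n_keep;
    for (int k = 0; k < K; ++k) cls_prob(j, k) /= n_keep;
  }
  for (int k = 0; k < K; ++k) pi_mean[k] /= n_keep;
  for (int k = 0; k < q; ++k) b_mean[k] /= n_keep;

  return List::create(
    _["effect"] = a_mean, _["class_prob"] = cls_prob,
    _["pi"] = pi_mean, _["fixed"] = b_mean,
    _["sigma2_e"] = s2e_mean / n_keep,
    _["sigma2_a"] = s2a_mean / n_keep,
    _["sigma2_g"] = s2g_mean / n_keep,
    _["n_samples"] = n_keep);
}
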