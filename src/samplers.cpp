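#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian draw (Michael, Schucany & Haas 1976), using R's RNG so
// results are governed by set.seed() on the R side.
static double rinvgauss(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y +
                                             mu * mu * y * y);
  if (!(x > 0.0)) x = 1e-12;
  double u = unif_rand();
  return (u <= mu / (mu + x)) ? x : mu * mu / x;
}

static double rscinvchisq(double df, double scale_sum) {
  // draw from scaled inverse chi-square: scale_sum / chisq(df)
  double c = R::rchisq(df);
  if (c < 1e-12) c = 1e-12;
  return scale_sum / c;
}

// shared Gaussian update of one marker effect given residual e (which
// EXCLUDES nothing: e is the full residual y - mu - X beta). Returns the
// new beta_j and updates e in place.
static double update_beta(const double* xj, int n, double xtx, double& e0,
                          double* e, double beta_old, double prior_prec,
                          double s2e) {
  (void)e0;
  double rhs = 0.0;
  for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
  rhs += xtx * beta_old;
  double prec = xtx / s2e + prior_prec;
  double mean = (rhs / s2e) / prec;
  double bnew = mean + norm_rand() / std::sqrt(prec);
  double diff = beta_old - bnew;
  for (int i = 0; i < n; ++i) e[i] += xj[i] * diff;
  return bnew;
}

static void update_mu(double& mu, std::vector<double>& e, double s2e) {
  int n = e.size();
  double ebar = 0.0;
  for (int i = 0; i < n; ++i) ebar += e[i];
  ebar /= n;
  double mu_new = mu + ebar + norm_rand() * std::sqrt(s2e / n);
  double shift = mu - mu_new + ebar; // new residual mean must drop ebar
  for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
  (void)shift;
  mu = mu_new;
}

static double update_s2e(const std::vector<double>& e, double nu0, double S0) {
  double sse = 0.0;
  for (size_t i = 0; i < e.size(); ++i) sse += e[i] * e[i];
  return rscinvchisq(e.size() + nu0, sse + nu0 * S0);
}

// [[Rcpp::export(name = ".gibbs_bl")]]
List gibbs_bl(NumericMatrix X, NumericVector y, int niter, int burnin,
              double r_lambda, double delta_lambda, double nu_e, double S_e) {
  int n = X.nrow(), m = X.ncol();
  std::vector<double> beta(m, 0.0), tau2(m, 1.0);
  double mu = mean(y), lambda2 = 1.0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = S_e;
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  NumericVector beta_mean(m, 0.0);
  double mu_mean = 0.0, s2e_mean = 0.0;
  int kept = 0;
  for (int it = 0; it < niter; ++it) {
    update_mu(mu, e, s2e);
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0) continue;
      const double* xj = &X(0, j);
      beta[j] = update_beta(xj, n, xtx[j], s2e, e.data(), beta[j],
                            1.0 / tau2[j], s2e);
    }
    double tau2_sum = 0.0;
    for (int j = 0; j < m; ++j) {
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-12) b2 = 1e-12;
      double inv = rinvgauss(std::sqrt(lambda2 / b2), lambda2);
      tau2[j] = 1.0 / inv;
      tau2_sum += tau2[j];
    }
    lambda2 = R::rgamma(r_lambda + m, 1.0 / (delta_lambda + tau2_sum / 2.0));
    s2e = update_s2e(e, nu_e, S_e);
    if (it >= burnin) {
      ++kept;
      for (int j = 0; j < m; ++j) beta_mean[j] += beta[j];
      mu_mean += mu;
      s2e_mean += s2e;
    }
  }
  for (int j = 0; j < m; ++j) beta_mean[j] /= kept;
  return List::create(_["mu"] = mu_mean / kept, _["beta"] = beta_mean,
                      _["sigma2_e"] = s2e_mean / kept,
                      _["n_samples"] = kept);
}

// [[Rcpp::export(name = ".gibbs_ebl")]]
List gibbs_ebl(NumericMatrix X, NumericVector y, int niter, int burnin,
               double phi, double omega, double psi, double theta,
               double nu_e, double S_e) {
  int n = X.nrow(), m = X.ncol();
  std::vector<double> beta(m, 0.0), tau2(m, 1.0), eta2(m, 1.0);
  double mu = mean(y), delta2 = 1.0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = S_e;
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  NumericVector beta_mean(m, 0.0);
  double mu_mean = 0.0, s2e_mean = 0.0;
  int kept = 0;
  for (int it = 0; it < niter; ++it) {
    update_mu(mu, e, s2e);
    for (int j = 0; j < m; ++j) {
      if (xtx[j] <= 0) continue;
      const double* xj = &X(0, j);
      beta[j] = update_beta(xj, n, xtx[j], s2e, e.data(), beta[j],
                            1.0 / tau2[j], s2e);
    }
    double et_sum = 0.0;
    for (int j = 0; j < m; ++j) {
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-12) b2 = 1e-12;
      double rate = delta2 * eta2[j];
      double inv = rinvgauss(std::sqrt(rate / b2), rate);
      tau2[j] = 1.0 / inv;
      eta2[j] = R::rgamma(psi + 1.0, 1.0 / (theta + delta2 * tau2[j] / 2.0));
      et_sum += eta2[j] * tau2[j];
    }
    delta2 = R::rgamma(phi + m, 1.0 / (omega + et_sum / 2.0));
    s2e = update_s2e(e, nu_e, S_e);
    if (it >= burnin) {
      ++kept;
      for (int j = 0; j < m; ++j) beta_mean[j] += beta[j];
      mu_mean += mu;
      s2e_mean += s2e;
    }
  }
  for (int j = 0; j < m; ++j) beta_mean[j] /= kept;
  return List::create(_["mu"] = mu_mean / kept, _["beta"] = beta_mean,
                      _["sigma2_e"] = s2e_mean / kept,
                      _["n_samples"] = kept);
}

// [[Rcpp::export(name = ".gibbs_bayesc")]]
List gibbs_bayesc(NumericMatrix X, NumericVector y, int niter, int burnin,
                  double pi_init, bool estimate_pi, double nu_b, double S_b,
                  double nu_e, double S_e) {
  int n = X.nrow(), m = X.ncol();
  std::vector<double> beta(m, 0.0);
  std::vector<int> gamma(m, 0);
  double mu = mean(y), s2b = S_b, piv = pi_init;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = S_e;
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  NumericVector beta_mean(m, 0.0), pip(m, 0.0);
  double mu_mean = 0.0, s2e_mean = 0.0, pi_mean = 0.0;
  int kept = 0;
  for (int it = 0; it < niter; ++it) {
    update_mu(mu, e, s2e);
    int m_in = 0;
    double ssb = 0.0;
    for (int j = 0; j < m; ++j) {
      double c = xtx[j];
      if (c <= 0) continue;
      const double* xj = &X(0, j);
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += c * beta[j];
      // marginal density of rhs: N(0, c*s2e) if excluded,
      // N(0, c^2*s2b + c*s2e) if included
      double v0 = c * s2e, v1 = c * c * s2b + c * s2e;
      double logbf = 0.5 * (std::log(v0) - std::log(v1)) +
                     0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
      double lodds = std::log(piv / (1.0 - piv)) + logbf;
      double p1 = 1.0 / (1.0 + std::exp(-lodds));
      int g = (unif_rand() < p1) ? 1 : 0;
      double bnew = 0.0;
      if (g) {
        double prec = c / s2e + 1.0 / s2b;
        double mn = (rhs / s2e) / prec;
        bnew = mn + norm_rand() / std::sqrt(prec);
        ++m_in;
        ssb += bnew * bnew;
      }
      double diff = beta[j] - bnew;
      if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] += xj[i] * diff;
      beta[j] = bnew;
      gamma[j] = g;
    }
    s2b = rscinvchisq(nu_b + m_in, nu_b * S_b + ssb);
    if (estimate_pi) {
      double a = R::rgamma(1.0 + m_in, 1.0);
      double b = R::rgamma(1.0 + m - m_in, 1.0);
      piv = a / (a + b);
      if (piv < 1e-6) piv = 1e-6;
      if (piv > 1.0 - 1e-6) piv = 1.0 - 1e-6;
    }
    s2e = update_s2e(e, nu_e, S_e);
    if (it >= burnin) {
      ++kept;
      for (int j = 0; j < m; ++j) {
        beta_mean[j] += beta[j];
        pip[j] += gamma[j];
      }
      mu_mean += mu;
      s2e_mean += s2e;
      pi_mean += piv;
    }
  }
  for (int j = 0; j < m; ++j) {
    beta_mean[j] /= kept;
    pip[j] /= kept;
  }
  return List::create(_["mu"] = mu_mean / kept, _["beta"] = beta_mean,
                      _["pip"] = pip, _["pi"] = pi_mean / kept,
                      _["sigma2_e"] = s2e_mean / kept,
                      _["n_samples"] = kept);
}
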