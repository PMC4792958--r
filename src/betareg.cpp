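// Maximum-likelihood beta regression with a logit mean link and an
// intercept-only log-link precision, fitted by Fisher scoring with step
// halving. One call fits many response vectors (probes) against a shared
// design matrix, which is what the per-CpG scan needs.
//
// Mean submodel: logit(mu_i) = x_i' b ; precision: log(phi) = g.
// Standard errors come from the observed information at the optimum
// (expected information as fallback if it is not invertible).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double beta_loglik(const vec& y, const mat& X, const vec& b, double g) {
  vec eta = X * b;
  vec mu = 1.0 / (1.0 + exp(-eta));
  double phi = std::exp(g);
  vec a = mu * phi, bb = (1.0 - mu) * phi;
  double ll = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    ll += std::lgamma(phi) - std::lgamma(a[i]) - std::lgamma(bb[i]) +
          (a[i] - 1.0) * std::log(y[i]) + (bb[i] - 1.0) * std::log1p(-y[i]);
  }
  return ll;
}

struct FitResult {
  vec theta;      // (b, g)
  vec se;
  double loglik;
  bool converged;
  int iterations;
};

static FitResult fit_one(const vec& y, const mat& X,
                         int maxit, double tol) {
  const uword n = y.n_elem, k = X.n_cols;
  FitResult res;
  res.theta.set_size(k + 1);
  res.se.set_size(k + 1);
  res.theta.fill(datum::nan);
  res.se.fill(datum::nan);
  res.loglik = datum::nan;
  res.converged = false;
  res.iterations = 0;

  vec ystar = log(y / (1.0 - y));

  // init: least squares on the logit scale, method-of-moments precision
  vec b;
  if (!solve(b, X.t() * X, X.t() * ystar)) return res;
  vec eta = X * b;
  vec mu0 = 1.0 / (1.0 + exp(-eta));
  double dfres = std::max((double)n - (double)k, 1.0);
  double s2 = dot(ystar - eta, ystar - eta) / dfres;
  double phi0 = 0.0;
  for (uword i = 0; i < n; ++i) {
    double t = mu0[i] * (1.0 - mu0[i]);
    phi0 += std::max(1.0 / (s2 * t) - 1.0, 0.01);
  }
  phi0 /= n;
  double g = std::log(std::max(phi0, 0.01));
  if (g > 12.0) g = 12.0;

  double ll = beta_loglik(y, X, b, g);
  bool grad_small = false;

  for (int iter = 1; iter <= maxit; ++iter) {
    res.iterations = iter;
    eta = X * b;
    vec mu = 1.0 / (1.0 + exp(-eta));
    double phi = std::exp(g);
    vec t = mu % (1.0 - mu);
    vec p1(n), p2(n), tg1(n), tg2(n);
    for (uword i = 0; i < n; ++i) {
      p1[i] = R::digamma(mu[i] * phi);
      p2[i] = R::digamma((1.0 - mu[i]) * phi);
      tg1[i] = R::trigamma(mu[i] * phi);
      tg2[i] = R::trigamma((1.0 - mu[i]) * phi);
    }
    vec mustar = p1 - p2;
    vec r = ystar - mustar;

    vec score(k + 1);
    score.head(k) = phi * (X.t() * (t % r));
    double sg = 0.0;
    double dg_phi = R::digamma(phi);
    for (uword i = 0; i < n; ++i)
      sg += mu[i] * r[i] + std::log1p(-y[i]) - p2[i] + dg_phi;
    score[k] = phi * sg;

    // expected information
    vec avec = tg1 + tg2;
    mat K(k + 1, k + 1, fill::zeros);
    mat Xw = X.each_col() % (phi * phi * avec % t % t);
    K.submat(0, 0, k - 1, k - 1) = X.t() * Xw;
    vec cvec = phi * phi * (t % (tg1 % mu - tg2 % (1.0 - mu)));
    K.submat(0, k, k - 1, k) = X.t() * cvec;
    K.submat(k, 0, k, k - 1) = (X.t() * cvec).t();
    double kgg = 0.0;
    double tg_phi = R::trigamma(phi);
    for (uword i = 0; i < n; ++i)
      kgg += mu[i] * mu[i] * tg1[i] + (1.0 - mu[i]) * (1.0 - mu[i]) * tg2[i] - tg_phi;
    K(k, k) = phi * phi * kgg;

    vec step;
    if (!solve(step, K, score)) {
      // ridge fallback
      K.diag() += 1e-8 * (abs(K.diag()) + 1.0);
      if (!solve(step, K, score)) break;
    }

    // step halving on the log-likelihood
    double sfac = 1.0;
    double ll_new = datum::nan;
    vec b_new; double g_new = g;
    for (int h = 0; h < 40; ++h) {
      b_new = b + sfac * step.head(k);
      g_new = g + sfac * step[k];
      if (g_new > 15.0) g_new = 15.0;
      if (g_new < -10.0) g_new = -10.0;
      ll_new = beta_loglik(y, X, b_new, g_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      sfac *= 0.5;
    }
    if (!std::isfinite(ll_new)) break;
    double dll = std::fabs(ll_new - ll);
    b = b_new; g = g_new; ll = ll_new;
    grad_small = norm(score, "inf") < tol * (1.0 + std::fabs(ll));
    if (dll < 1e-10 * (std::fabs(ll) + 1.0) || grad_small) {
      res.converged = true;
      break;
    }
  }

  // observed information at the optimum for the covariance
  eta = X * b;
  vec mu = 1.0 / (1.0 + exp(-eta));
  double phi = std::exp(g);
  vec t = mu % (1.0 - mu);
  vec p1(n), p2(n), tg1(n), tg2(n);
  for (uword i = 0; i < n; ++i) {
    p1[i] = R::digamma(mu[i] * phi);
    p2[i] = R::digamma((1.0 - mu[i]) * phi);
    tg1[i] = R::trigamma(mu[i] * phi);
    tg2[i] = R::trigamma((1.0 - mu[i]) * phi);
  }
  vec r = ystar - (p1 - p2);
  vec avec = tg1 + tg2;
  mat J(k + 1, k + 1, fill::zeros);
  vec wbb = phi * (t % (phi * avec % t - r % (1.0 - 2.0 * mu)));
  J.submat(0, 0, k - 1, k - 1) = X.t() * (X.each_col() % wbb);
  vec wbg = phi * (t % (phi * (tg1 % mu - tg2 % (1.0 - mu)) - r));
  J.submat(0, k, k - 1, k) = X.t() * wbg;
  J.submat(k, 0, k, k - 1) = (X.t() * wbg).t();
  double sg = 0.0, jgg = 0.0;
  double dg_phi = R::digamma(phi), tg_phi = R::trigamma(phi);
  for (uword i = 0; i < n; ++i) {
    sg += mu[i] * r[i] + std::log1p(-y[i]) - p2[i] + dg_phi;
    jgg += mu[i] * mu[i] * tg1[i] + (1.0 - mu[i]) * (1.0 - mu[i]) * tg2[i] - tg_phi;
  }
  J(k, k) = phi * phi * jgg - phi * sg;

  mat Vcov;
  bool ok = inv_sympd(Vcov, symmatu(J));
  if (!ok) ok = inv(Vcov, symmatu(J));
  if (ok) {
    vec d = Vcov.diag();
    for (uword j = 0; j <= k; ++j)
      res.se[j] = d[j] > 0 ? std::sqrt(d[j]) : datum::nan;
  }
  res.theta.head(k) = b;
  res.theta[k] = g;
  res.loglik = ll;
  return res;
}

// [[Rcpp::export(name = ".beta_reg_batch")]]
Rcpp::List beta_reg_batch(const arma::mat& Y, const arma::mat& X,
                          double eps = 1e-6, int maxit = 100,
                          double tol = 1e-8) {
  const uword m = Y.n_rows, k = X.n_cols;
  arma::mat coef(m, k + 1, fill::value(datum::nan));
  arma::mat se(m, k + 1, fill::value(datum::nan));
  arma::vec loglik(m, fill::value(datum::nan));
  Rcpp::LogicalVector converged(m);
  Rcpp::IntegerVector iterations(m);
  for (uword i = 0; i < m; ++i) {
    vec y = Y.row(i).t();
    y = clamp(y, eps, 1.0 - eps);
    if (y.max() - y.min() < 1e-12) {  // constant probe: not fittable
      converged[i] = false;
      continue;
    }
    FitResult f = fit_one(y, X, maxit, tol);
    coef.row(i) = f.theta.t();
    se.row(i) = f.se.t();
    loglik[i] = f.loglik;
    converged[i] = f.converged;
    iterations[i] = f.iterations;
  }
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = coef,
    Rcpp::Named("se") = se,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iterations);
}
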