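// Marginal log-likelihood, score and observed information for a
// binary-outcome mixed model with correlated random intercept and slope,
// integrated by adaptive Gauss-Hermite quadrature centred at each subject's
// posterior mode.
//
// Parameter vector: c(beta, l1, l21, l2) where the random-effect covariance
// is Sigma = L L' with L = [[exp(l1), 0], [l21, exp(l2)]] (log-Cholesky).
//
// Score and information use the quadrature-weighted posterior identities
//   d log L_i = E[dh],   d2 log L_i = E[d2h] + Cov(dh)
// with expectations over the normalised node weights; the joint log-density
// h separates into an observation part (beta only) and a Gaussian prior
// part (Cholesky parameters only), so E[d2h] is block diagonal.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log-likelihood of one observation and its first two derivatives in the
// linear predictor eta
static inline void obs_derivs(double eta, double y, int link,
                              double &ll, double &d1, double &d2) {
  if (link == 0) { // probit
    if (y > 0.5) {
      double lp = R::pnorm(eta, 0.0, 1.0, 1, 1); // log Phi
      double r  = std::exp(R::dnorm(eta, 0.0, 1.0, 1) - lp);
      ll = lp; d1 = r; d2 = -r * (r + eta);
    } else {
      double lp = R::pnorm(eta, 0.0, 1.0, 0, 1); // log(1 - Phi)
      double s  = std::exp(R::dnorm(eta, 0.0, 1.0, 1) - lp);
      ll = lp; d1 = -s; d2 = -s * (s - eta);
    }
  } else { // logit
    double p = 1.0 / (1.0 + std::exp(-eta));
    ll = (y > 0.5) ? -std::log1p(std::exp(-eta)) : -std::log1p(std::exp(eta));
    d1 = y - p;
    d2 = -p * (1.0 - p);
  }
}

struct PriorInfo {
  double a, c, d, s;       // L entries and exp(-l2)
  arma::mat Linv, Siginv;
  double logdetL;
};

// h(b) = sum_j ll_j + log N2(b; 0, Sigma)
static double joint_h(const arma::vec &eta0, const arma::vec &tv,
                      const arma::vec &yv, int link, const arma::vec &b,
                      const PriorInfo &pr) {
  double ll, d1, d2, h = 0.0;
  for (arma::uword j = 0; j < eta0.n_elem; ++j) {
    obs_derivs(eta0[j] + b[0] + b[1] * tv[j], yv[j], link, ll, d1, d2);
    h += ll;
  }
  double q = arma::as_scalar(b.t() * pr.Siginv * b);
  return h - std::log(2.0 * M_PI) - pr.logdetL - 0.5 * q;
}

// [[Rcpp::export]]
List nlmm_objective_cpp(const arma::vec &par, const arma::mat &X,
                        const arma::vec &tvec, const arma::vec &y,
                        const arma::ivec &sub_start, const arma::ivec &sub_len,
                        int link, const arma::vec &gh_x, const arma::vec &gh_w,
                        bool want_grad, bool want_hess) {
  const arma::uword p = X.n_cols;
  const arma::uword np = p + 3;
  arma::vec beta = par.subvec(0, p - 1);
  double l1 = par[p], l21 = par[p + 1], l2 = par[p + 2];
  if (want_hess) want_grad = true;

  PriorInfo pr;
  pr.a = std::exp(l1); pr.c = l21; pr.d = std::exp(l2); pr.s = std::exp(-l2);
  arma::mat L(2, 2, arma::fill::zeros);
  L(0, 0) = pr.a; L(1, 0) = pr.c; L(1, 1) = pr.d;
  pr.logdetL = l1 + l2;
  pr.Linv = arma::inv(arma::trimatl(L));
  pr.Siginv = pr.Linv.t() * pr.Linv;

  arma::vec eta_all = X * beta;
  const int n_nodes = gh_x.n_elem;
  arma::vec lwstar(n_nodes); // log(w) + x^2: weights for unit integrand
  for (int k = 0; k < n_nodes; ++k) lwstar[k] = std::log(gh_w[k]) + gh_x[k] * gh_x[k];

  const double sqrt2 = std::sqrt(2.0);
  const arma::uword nsub = sub_start.n_elem;
  double total = 0.0;
  arma::vec grad(np, arma::fill::zeros);
  arma::mat hess(np, np, arma::fill::zeros);
  double ll, d1, d2;

  arma::vec gk(np), gbar(np);
  arma::mat Hk(np, np), Hbar(np, np), ggbar(np, np);

  for (arma::uword i = 0; i < nsub; ++i) {
    arma::uword s0 = (arma::uword)sub_start[i];
    arma::uword ni = (arma::uword)sub_len[i];
    arma::vec eta0 = eta_all.subvec(s0, s0 + ni - 1);
    arma::vec tv = tvec.subvec(s0, s0 + ni - 1);
    arma::vec yv = y.subvec(s0, s0 + ni - 1);

    // posterior mode of the random effects by damped Newton
    arma::vec b(2, arma::fill::zeros);
    double h_cur = joint_h(eta0, tv, yv, link, b, pr);
    arma::mat Hn(2, 2);
    for (int iter = 0; iter < 60; ++iter) {
      arma::vec g(2, arma::fill::zeros);
      arma::mat Hb(2, 2, arma::fill::zeros);
      for (arma::uword j = 0; j < ni; ++j) {
        obs_derivs(eta0[j] + b[0] + b[1] * tv[j], yv[j], link, ll, d1, d2);
        g[0] += d1;          g[1] += d1 * tv[j];
        Hb(0, 0) += d2;      Hb(0, 1) += d2 * tv[j];
        Hb(1, 1) += d2 * tv[j] * tv[j];
      }
      Hb(1, 0) = Hb(0, 1);
      g -= pr.Siginv * b;
      Hn = -(Hb - pr.Siginv); // positive semi-definite; can degenerate when
                              // both the prior and the data curvature vanish
      Hn.diag() += 1e-8 * (1.0 + arma::trace(Hn));
      if (arma::norm(g, "inf") < 1e-9) break;
      arma::vec step = arma::solve(Hn, g, arma::solve_opts::likely_sympd);
      double sc = 1.0;
      for (int ls = 0; ls < 40; ++ls) {
        arma::vec bt = b + sc * step;
        double h_try = joint_h(eta0, tv, yv, link, bt, pr);
        if (h_try >= h_cur - 1e-12) { b = bt; h_cur = h_try; break; }
        sc *= 0.5;
      }
    }
    { // curvature at the final mode
      arma::mat Hb(2, 2, arma::fill::zeros);
      for (arma::uword j = 0; j < ni; ++j) {
        obs_derivs(eta0[j] + b[0] + b[1] * tv[j], yv[j], link, ll, d1, d2);
        Hb(0, 0) += d2; Hb(0, 1) += d2 * tv[j]; Hb(1, 1) += d2 * tv[j] * tv[j];
      }
      Hb(1, 0) = Hb(0, 1);
      Hn = -(Hb - pr.Siginv);
    }
    arma::mat R;
    double jitter = 0.0;
    while (!arma::chol(R, Hn)) {
      jitter = (jitter == 0.0) ? 1e-8 * (1.0 + std::abs(arma::trace(Hn)))
                               : jitter * 10.0;
      if (jitter > 1e6)
        stop("non-positive-definite curvature at subject %d", (int)i + 1);
      Hn.diag() += jitter;
    }
    arma::mat A = arma::inv(arma::trimatu(R)); // A A' = Hn^{-1}

    double S = 0.0;
    gbar.zeros(); Hbar.zeros(); ggbar.zeros();
    for (int k1 = 0; k1 < n_nodes; ++k1) {
      for (int k2 = 0; k2 < n_nodes; ++k2) {
        arma::vec u = {gh_x[k1], gh_x[k2]};
        arma::vec bk = b + sqrt2 * (A * u);
        // single pass: h, and per-parameter first/second derivatives
        double hk = 0.0;
        if (want_grad) { gk.zeros(); }
        if (want_hess) { Hk.zeros(); }
        for (arma::uword j = 0; j < ni; ++j) {
          obs_derivs(eta0[j] + bk[0] + bk[1] * tv[j], yv[j], link, ll, d1, d2);
          hk += ll;
          if (want_grad)
            for (arma::uword m = 0; m < p; ++m) gk[m] += d1 * X(s0 + j, m);
          if (want_hess)
            for (arma::uword m = 0; m < p; ++m)
              for (arma::uword m2 = 0; m2 <= m; ++m2)
                Hk(m, m2) += d2 * X(s0 + j, m) * X(s0 + j, m2);
        }
        // Gaussian prior: value and derivatives in (l1, l21, l2)
        double v1 = pr.Linv(0, 0) * bk[0];
        double v2 = pr.Linv(1, 0) * bk[0] + pr.Linv(1, 1) * bk[1];
        hk += -std::log(2.0 * M_PI) - pr.logdetL - 0.5 * (v1 * v1 + v2 * v2);
        if (want_grad) {
          gk[p]     = v1 * v1 - pr.c * pr.s * v1 * v2 - 1.0;
          gk[p + 1] = pr.s * v1 * v2;
          gk[p + 2] = v2 * v2 - 1.0;
        }
        if (want_hess) {
          double cs = pr.c * pr.s;
          Hk(p, p)         = -(2.0 * v1 * v1 + cs * cs * v1 * v1 - cs * v1 * v2);
          Hk(p + 1, p)     = -(-cs * pr.s * v1 * v1 + pr.s * v1 * v2);
          Hk(p + 1, p + 1) = -(pr.s * pr.s * v1 * v1);
          Hk(p + 2, p)     = -(-2.0 * cs * v1 * v2);
          Hk(p + 2, p + 1) = -(2.0 * pr.s * v1 * v2);
          Hk(p + 2, p + 2) = -(2.0 * v2 * v2);
        }
        double w = std::exp(lwstar[k1] + lwstar[k2] + hk - h_cur);
        S += w;
        if (want_grad) gbar += w * gk;
        if (want_hess) {
          Hbar += w * Hk;
          for (arma::uword m = 0; m < np; ++m)
            for (arma::uword m2 = 0; m2 <= m; ++m2)
              ggbar(m, m2) += w * gk[m] * gk[m2];
        }
      }
    }
    total += std::log(2.0) - std::log(R(0, 0)) - std::log(R(1, 1)) + h_cur + std::log(S);
    if (want_grad) {
      gbar /= S;
      grad += gbar;
    }
    if (want_hess) {
      Hbar /= S; ggbar /= S;
      for (arma::uword m = 0; m < np; ++m)
        for (arma::uword m2 = 0; m2 <= m; ++m2)
          hess(m, m2) += Hbar(m, m2) + ggbar(m, m2) - gbar[m] * gbar[m2];
    }
  }

  if (!std::isfinite(total)) stop("non-finite marginal log-likelihood");
  if (want_hess)
    return List::create(_["loglik"] = total, _["gradient"] = grad,
                        _["hessian"] = arma::symmatl(hess));
  if (want_grad)
    return List::create(_["loglik"] = total, _["gradient"] = grad);
  return List::create(_["loglik"] = total);
}

// Plain (no random effects) binary-regression log-likelihood, used when the
// random-effect covariance is exactly zero.
// [[Rcpp::export]]
double glm_loglik_cpp(const arma::vec &beta, const arma::mat &X,
                      const arma::vec &y, int link) {
  arma::vec eta = X * beta;
  double ll, d1, d2, total = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    obs_derivs(eta[j], y[j], link, ll, d1, d2);
    total += ll;
  }
  return total;
}
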