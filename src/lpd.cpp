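#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Per-signature Gaussian log-densities, cube G x A x K.
// [[Rcpp::export]]
arma::cube cpp_log_dens(const arma::mat& X, const arma::mat& mu,
                        const arma::mat& sigma2) {
  const arma::uword G = X.n_rows, A = X.n_cols, K = mu.n_cols;
  arma::cube out(G, A, K);
  const double l2pi = std::log(2.0 * M_PI);
  for (arma::uword k = 0; k < K; ++k) {
    arma::vec c0 = -0.5 * (l2pi + arma::log(sigma2.col(k)));
    arma::vec inv2 = 0.5 / sigma2.col(k);
    arma::mat& sl = out.slice(k);
    for (arma::uword a = 0; a < A; ++a) {
      arma::vec d = X.col(a) - mu.col(k);
      sl.col(a) = c0 - inv2 % (d % d);
    }
  }
  return out;
}

static arma::mat digamma_mat(const arma::mat& x) {
  arma::mat out(x.n_rows, x.n_cols);
  for (arma::uword i = 0; i < x.n_elem; ++i) out(i) = R::digamma(x(i));
  return out;
}

// Coordinate ascent on (Q, gamma) with model parameters fixed.
// logdens: G x A x K cube; alpha: K; gamma0: A x K.
// Iterates  Q_kga  proportional to  exp(logdens_gak + psi(gamma_ak)),
// normalised over k, then  gamma_ak = alpha_k + sum_g Q_kga,
// until max |delta gamma| < tol or maxInner sweeps.
// [[Rcpp::export]]
List cpp_e_step(const arma::cube& logdens, const arma::vec& alpha,
                const arma::mat& gamma0, const int maxInner,
                const double tol) {
  const arma::uword G = logdens.n_rows, A = logdens.n_cols,
                    K = logdens.n_slices;
  arma::mat gamma = gamma0;
  arma::cube Q(G, A, K);
  int it = 0;
  bool conv = false;
  for (it = 1; it <= maxInner; ++it) {
    arma::mat dg = digamma_mat(gamma);  // A x K
    // W = logdens + psi(gamma), broadcast over genes
    arma::mat M(G, A, arma::fill::value(-arma::datum::inf));
    for (arma::uword k = 0; k < K; ++k) {
      arma::mat& sl = Q.slice(k);
      sl = logdens.slice(k);
      sl.each_row() += dg.col(k).t();
      M = arma::max(M, sl);
    }
    arma::mat S(G, A, arma::fill::zeros);
    for (arma::uword k = 0; k < K; ++k) {
      Q.slice(k) = arma::exp(Q.slice(k) - M);
      S += Q.slice(k);
    }
    arma::mat gnew(A, K);
    for (arma::uword k = 0; k < K; ++k) {
      Q.slice(k) /= S;
      gnew.col(k) = arma::sum(Q.slice(k), 0).t() + alpha(k);
    }
    double delta = arma::abs(gnew - gamma).max();
    gamma = gnew;
    if (delta < tol) { conv = true; break; }
  }
  if (!conv) it = maxInner;
  return List::create(_["Q"] = Q, _["gamma"] = gamma,
                      _["iterations"] = it, _["converged"] = conv);
}

// Responsibility-weighted Gaussian updates. Zero-weight (g,k) cells are
// reset to the gene's global mean/variance and counted.
// [[Rcpp::export]]
List cpp_m_step(const arma::mat& X, const arma::cube& Q,
                const double varFloor) {
  const arma::uword G = X.n_rows, A = X.n_cols, K = Q.n_slices;
  arma::mat mu(G, K), sigma2(G, K);
  arma::vec gmean = arma::mean(X, 1);
  arma::vec gvar(G);
  for (arma::uword g = 0; g < G; ++g) {
    arma::rowvec d = X.row(g) - gmean(g);
    gvar(g) = arma::dot(d, d) / A;
  }
  int resets = 0;
  for (arma::uword k = 0; k < K; ++k) {
    const arma::mat& q = Q.slice(k);
    arma::vec w = arma::sum(q, 1);
    arma::vec num = arma::sum(q % X, 1);
    for (arma::uword g = 0; g < G; ++g) {
      if (w(g) <= 0.0) {
        mu(g, k) = gmean(g);
        sigma2(g, k) = std::max(gvar(g), varFloor);
        ++resets;
      } else {
        mu(g, k) = num(g) / w(g);
      }
    }
    for (arma::uword g = 0; g < G; ++g) {
      if (w(g) <= 0.0) continue;
      double acc = 0.0;
      for (arma::uword a = 0; a < A; ++a) {
        double d = X(g, a) - mu(g, k);
        acc += q(g, a) * d * d;
      }
      sigma2(g, k) = std::max(acc / w(g), varFloor);
    }
  }
  return List::create(_["mu"] = mu, _["sigma2"] = sigma2,
                      _["resets"] = resets);
}

// Evidence lower bound for the Dirichlet/Gaussian mixed-membership model.
// [[Rcpp::export]]
double cpp_elbo(const arma::cube& logdens, const arma::cube& Q,
                const arma::mat& gamma, const arma::vec& alpha) {
  const arma::uword G = logdens.n_rows, A = logdens.n_cols,
                    K = logdens.n_slices;
  arma::vec gsum = arma::sum(gamma, 1);
  arma::mat elog(A, K);  // E[log theta_ak]
  for (arma::uword a = 0; a < A; ++a) {
    double d0 = R::digamma(gsum(a));
    for (arma::uword k = 0; k < K; ++k)
      elog(a, k) = R::digamma(gamma(a, k)) - d0;
  }
  double bound = 0.0;
  for (arma::uword k = 0; k < K; ++k) {
    const arma::mat& q = Q.slice(k);
    const arma::mat& ld = logdens.slice(k);
    for (arma::uword a = 0; a < A; ++a) {
      double el = elog(a, k);
      for (arma::uword g = 0; g < G; ++g) {
        double qq = q(g, a);
        if (qq > 0.0) bound += qq * (ld(g, a) + el - std::log(qq));
      }
    }
  }
  double asum = arma::sum(alpha);
  double cst = R::lgammafn(asum);
  for (arma::uword k = 0; k < K; ++k) cst -= R::lgammafn(alpha(k));
  bound += A * cst;
  for (arma::uword a = 0; a < A; ++a) {
    double t = -R::lgammafn(gsum(a));
    for (arma::uword k = 0; k < K; ++k) {
      t += R::lgammafn(gamma(a, k));
      t += (alpha(k) - gamma(a, k)) * elog(a, k);
    }
    bound += t;
  }
  return bound;
}

// Predictive log-likelihood sum_g log sum_k theta_k N(e_ga; mu_gk, s2_gk)
// per sample, given per-sample mixing proportions theta (A x K).
// [[Rcpp::export]]
arma::vec cpp_predictive_loglik(const arma::cube& logdens,
                                const arma::mat& theta) {
  const arma::uword G = logdens.n_rows, A = logdens.n_cols,
                    K = logdens.n_slices;
  arma::vec out(A, arma::fill::zeros);
  arma::mat lt = arma::log(theta);
  for (arma::uword a = 0; a < A; ++a) {
    for (arma::uword g = 0; g < G; ++g) {
      double m = -arma::datum::inf;
      for (arma::uword k = 0; k < K; ++k) {
        double v = logdens(g, a, k) + lt(a, k);
        if (v > m) m = v;
      }
      double s = 0.0;
      for (arma::uword k = 0; k < K; ++k)
        s += std::exp(logdens(g, a, k) + lt(a, k) - m);
      out(a) += m + std::log(s);
    }
  }
  return out;
}
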