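// Profile maximum likelihood for the two-level model
//   y = X beta + Z u + e,   u ~ N(0, tau00 I_g) on group labels,
//   e ~ N(0, sigma2 I_n)
// parameterized by lambda = tau00 / sigma2.  For a single grouping factor
// the covariance V* = I + lambda Z Z' is block diagonal, so GLS quantities
// reduce to per-group sums (Woodbury), giving O(g p^2 + p^3) per likelihood
// evaluation regardless of n.  This is what makes exhaustive subset search
// plus leave-one-client-out CV feasible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Pre {
  mat XtX;   // p x p
  vec Xty;   // p
  double yty;
  mat Gx;    // g x p, column sums of X per group
  vec Gy;    // g, sums of y per group
  vec nj;    // g, group sizes (may contain zeros after downdating)
  double n;
};

// Profile log-likelihood at lambda; fills beta-hat and the ML sigma2-hat.
double prof_eval(double lam, const Pre& P, vec& beta, double& sig2) {
  vec c = lam / (1.0 + lam * P.nj);
  mat Gxc = P.Gx.each_col() % c;
  mat A = P.XtX - P.Gx.t() * Gxc;
  vec b = P.Xty - P.Gx.t() * (P.Gy % c);
  double q0 = P.yty - dot(P.Gy % c, P.Gy);
  if (!solve(beta, A, b, solve_opts::no_approx)) return -datum::inf;
  double Q = q0 - dot(b, beta);
  if (Q < 1e-300) Q = 1e-300;  // exactly-deterministic data
  sig2 = Q / P.n;
  double ldet = sum(log1p(lam * P.nj));
  return -0.5 * P.n * std::log(2.0 * datum::pi)
       - 0.5 * P.n * std::log(sig2) - 0.5 * ldet - 0.5 * P.n;
}

// Golden-section maximization of the profile likelihood over log(lambda),
// with an explicit boundary check at lambda = 0.  The profile in log(lambda)
// is smooth and in practice unimodal for this model class; the bracket is
// contracted below 1e-10, far finer than any reported quantity resolves.
void optimize_lambda(const Pre& P, double& lam, vec& beta, double& sig2,
                     double& ll) {
  const double lo = -16.0, hi = 11.0;  // lambda in [1.1e-7, 6e4]
  const double gr = 0.61803398874989484;
  double a = lo, bnd = hi;
  double x1 = bnd - gr * (bnd - a), x2 = a + gr * (bnd - a);
  vec btmp;
  double stmp;
  double f1 = prof_eval(std::exp(x1), P, btmp, stmp);
  double f2 = prof_eval(std::exp(x2), P, btmp, stmp);
  // stop when the bracket is tight or the likelihood is flat across it
  // (golden contraction makes the ll gap shrink quadratically in the
  // bracket width, so a 1e-10 ll gap localizes the optimum far beyond
  // reporting precision); the lambda = 0 boundary is checked separately,
  // which also covers the flat small-lambda plateau of group-free data
  while (bnd - a > 1e-10 &&
         std::abs(f1 - f2) > 1e-10 * (std::abs(f1) + 1.0)) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (bnd - a);
      f2 = prof_eval(std::exp(x2), P, btmp, stmp);
    } else {
      bnd = x2; x2 = x1; f2 = f1;
      x1 = bnd - gr * (bnd - a);
      f1 = prof_eval(std::exp(x1), P, btmp, stmp);
    }
  }
  double xopt = 0.5 * (x1 + x2);
  double lam_opt = std::exp(xopt);
  double ll_opt = prof_eval(lam_opt, P, beta, sig2);
  // boundary: tau00 = 0
  vec beta0;
  double sig20;
  double ll0 = prof_eval(0.0, P, beta0, sig20);
  if (ll0 >= ll_opt - 1e-7) {
    lam = 0.0; beta = beta0; sig2 = sig20; ll = ll0;
  } else {
    lam = lam_opt; ll = ll_opt;
  }
}

Pre precompute(const mat& X, const vec& y, const ivec& grp, int ngrp) {
  Pre P;
  P.XtX = X.t() * X;
  P.Xty = X.t() * y;
  P.yty = dot(y, y);
  P.Gx.zeros(ngrp, X.n_cols);
  P.Gy.zeros(ngrp);
  P.nj.zeros(ngrp);
  for (uword i = 0; i < X.n_rows; ++i) {
    int g = grp(i);
    P.Gx.row(g) += X.row(i);
    P.Gy(g) += y(i);
    P.nj(g) += 1.0;
  }
  P.n = (double)X.n_rows;
  return P;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List lmm_profile_fit_cpp(const arma::mat& X, const arma::vec& y,
                               const arma::ivec& grp, int ngrp) {
  Pre P = precompute(X, y, grp, ngrp);
  double lam, sig2, ll;
  vec beta;
  optimize_lambda(P, lam, beta, sig2, ll);
  bool ok = std::isfinite(ll);
  // covariance of beta-hat: sigma2 * (X' V*^-1 X)^-1 at lambda-hat
  vec c = lam / (1.0 + lam * P.nj);
  mat A = P.XtX - P.Gx.t() * (P.Gx.each_col() % c);
  mat cov;
  if (!inv_sympd(cov, A)) {
    ok = inv(cov, A) && ok;
  }
  cov *= sig2;
  // conditional modes of the group intercepts: u_j = lam s_j / (1 + lam n_j)
  vec s = P.Gy - P.Gx * beta;
  vec blup = (lam * s) / (1.0 + lam * P.nj);
  blup.elem(find(P.nj == 0)).zeros();
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("cov") = cov,
      Rcpp::Named("sigma2") = sig2,
      Rcpp::Named("tau00") = lam * sig2,
      Rcpp::Named("lambda") = lam,
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("blup") = blup,
      Rcpp::Named("converged") = ok);
}

// Batch scoring for the subset search: fit many candidate column subsets of
// one full design matrix and return AIC, marginal R2, log-likelihood and a
// convergence flag per candidate.  Bypasses all per-fit R overhead.
// `sets` holds 0-based indices into the columns of X *excluding* the
// intercept column, which is X.col(0) and always included.
// [[Rcpp::export]]
Rcpp::NumericMatrix lmm_score_batch_cpp(const arma::mat& X, const arma::vec& y,
                                        const arma::ivec& grp, int ngrp,
                                        const Rcpp::List& sets) {
  int m = sets.size();
  Rcpp::NumericMatrix out(m, 4);
  colnames(out) = Rcpp::CharacterVector::create("aic", "r2", "loglik",
                                                "converged");
  for (int s = 0; s < m; ++s) {
    Rcpp::IntegerVector iv = sets[s];
    uvec cols(iv.size() + 1);
    cols(0) = 0;
    for (int j = 0; j < iv.size(); ++j) cols(j + 1) = (uword)(iv[j] + 1);
    mat Xs = X.cols(cols);
    Pre P = precompute(Xs, y, grp, ngrp);
    double lam, sig2, ll;
    vec beta;
    optimize_lambda(P, lam, beta, sig2, ll);
    // rank-deficient subsets make every GLS solve fail: flag, don't crash
    bool ok = std::isfinite(ll) && beta.n_elem == Xs.n_cols;
    if (ok) {
      vec eta = Xs * beta;
      double vf = arma::var(eta, 1);  // population variance, denominator n
      out(s, 0) = -2.0 * ll + 2.0 * (double)(Xs.n_cols + 2);
      out(s, 1) = vf / (vf + lam * sig2 + sig2);
      out(s, 2) = ll;
    } else {
      out(s, 0) = NA_REAL;
      out(s, 1) = NA_REAL;
      out(s, 2) = NA_REAL;
    }
    out(s, 3) = ok ? 1.0 : 0.0;
  }
  return out;
}

// Leave-one-row-out cross-validated predictions.  Each fold downdates the
// precomputed cross-products (the "streaming" path) and re-optimizes lambda
// from scratch, so every fold is a full ML refit.  cond = TRUE adds the
// held-out row's group conditional intercept when that group retains rows.
// [[Rcpp::export]]
arma::vec lmm_loocv_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::ivec& grp, int ngrp, bool cond) {
  Pre P = precompute(X, y, grp, ngrp);
  vec yhat(X.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    Pre Pi = P;
    rowvec x = X.row(i);
    int g = grp(i);
    Pi.XtX -= x.t() * x;
    Pi.Xty -= x.t() * y(i);
    Pi.yty -= y(i) * y(i);
    Pi.Gx.row(g) -= x;
    Pi.Gy(g) -= y(i);
    Pi.nj(g) -= 1.0;
    Pi.n -= 1.0;
    double lam, sig2, ll;
    vec beta;
    optimize_lambda(Pi, lam, beta, sig2, ll);
    if (!std::isfinite(ll) || beta.n_elem != X.n_cols) {
      yhat(i) = datum::nan;
      continue;
    }
    double pred = dot(x, beta);
    if (cond && Pi.nj(g) > 0) {
      double s = Pi.Gy(g) - dot(Pi.Gx.row(g), beta);
      pred += lam * s / (1.0 + lam * Pi.nj(g));
    }
    yhat(i) = pred;
  }
  return yhat;
}
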