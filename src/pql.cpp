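// Penalized quasi-likelihood core for the logistic mixed model
//   logit(mu) = X alpha + Z beta,  beta_k ~ N(0, tau2),
// and the permutation/bootstrap refit loop for the variance-component LRT.
//
// The working linear mixed model at each PQL step is profiled over tau2
// using one thin SVD of the R^{-1/2}-standardized Z per step, so each
// tau2 evaluation costs O(K p^2) instead of O(n^3).  This is what makes
// B x n_reps full refits (permutation null distributions inside
// Monte-Carlo studies) tractable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Profiled quasi log-likelihood (up to a constant) of the working LMM
//   Y' = X alpha + Z beta + e,  beta ~ N(0, tau2 I),  e ~ N(0, sigma2 R),
// at a given variance ratio lam = tau2 / sigma2, with the fixed effects
// profiled out by GLS and the residual scale sigma2 profiled in closed
// form (ML: qf/n; REML: qf/(n-p)).  All inputs are in the R^{-1/2}
// standardized basis: d = eigenvalues of Ztil' Ztil, A = U' Xtil,
// a = U' ytil, G0 = Xtil' Xtil, g0 = Xtil' ytil, yy = ytil' ytil.
double work_ll(double lam, const vec& d, const mat& A, const vec& a,
               const mat& G0, const vec& g0, double yy, double sumlogr,
               int n, bool reml, double* sig2_out, vec* alpha_out) {
  vec w = (lam * d) / (1.0 + lam * d);
  mat Gw = G0 - A.t() * (A.each_col() % w);
  vec gw = g0 - A.t() * (w % a);
  vec alpha;
  bool ok = solve(alpha, Gw, gw, solve_opts::no_approx);
  // near-singular GLS systems can arise in resampled refits when working
  // weights collapse; fall back to the minimum-norm solution
  if (!ok) alpha = pinv(Gw) * gw;
  double yMy = yy - dot(w, a % a);
  double qf = yMy - dot(alpha, gw);  // (Y'-Xa)' V1^{-1} (Y'-Xa), standardized
  if (qf < 1e-300) qf = 1e-300;
  double ll;
  double sig2;
  if (!reml) {
    sig2 = qf / n;
    ll = -0.5 * (n * std::log(sig2) + accu(log(1.0 + lam * d)) + sumlogr + n);
  } else {
    int df = n - (int)G0.n_cols;
    sig2 = qf / df;
    double ldet, sign;
    log_det(ldet, sign, Gw);  // log |X' V1^{-1} X|
    ll = -0.5 * (df * std::log(sig2) + accu(log(1.0 + lam * d)) + sumlogr +
                 ldet + df);
  }
  if (sig2_out) *sig2_out = sig2;
  if (alpha_out) *alpha_out = alpha;
  return ll;
}

struct WorkOpt {
  double lam;      // variance ratio tau2 / sigma2
  double sigma2;
  double tau2;     // lam * sigma2
  double ll_alt;
  double ll_null;
  vec alpha;
  bool boundary;
};

// Maximize the profiled quasi log-likelihood over tau2 in [0, upper]:
// coarse log-spaced grid to bracket, then golden-section refinement.
WorkOpt maximize_tau2(const vec& d, const mat& A, const vec& a,
                      const mat& G0, const vec& g0, double yy,
                      double sumlogr, int n, double upper, int n_grid,
                      bool reml) {
  WorkOpt out;
  out.ll_null = work_ll(0.0, d, A, a, G0, g0, yy, sumlogr, n, reml,
                        nullptr, nullptr);

  // grid over the variance ratio: 0 plus log-spaced points in [1e-5, upper]
  vec grid(n_grid + 1);
  grid(0) = 0.0;
  double glo = std::log(1e-5), ghi = std::log(upper);
  for (int i = 0; i < n_grid; ++i)
    grid(i + 1) = std::exp(glo + (ghi - glo) * i / (n_grid - 1.0));

  int ibest = 0;
  double llbest = out.ll_null;
  for (int i = 1; i <= n_grid; ++i) {
    double ll = work_ll(grid(i), d, A, a, G0, g0, yy, sumlogr, n, reml,
                        nullptr, nullptr);
    if (ll > llbest) { llbest = ll; ibest = i; }
  }

  double xl = grid(std::max(ibest - 1, 0));
  double xr = (ibest == n_grid) ? upper : grid(ibest + 1);
  // golden-section maximization on [xl, xr]
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double b1 = xr - gr * (xr - xl), b2 = xl + gr * (xr - xl);
  double f1 = work_ll(b1, d, A, a, G0, g0, yy, sumlogr, n, reml,
                      nullptr, nullptr);
  double f2 = work_ll(b2, d, A, a, G0, g0, yy, sumlogr, n, reml,
                      nullptr, nullptr);
  for (int it = 0; it < 80 && (xr - xl) > 1e-10 * (1.0 + xr); ++it) {
    if (f1 < f2) {
      xl = b1; b1 = b2; f1 = f2;
      b2 = xl + gr * (xr - xl);
      f2 = work_ll(b2, d, A, a, G0, g0, yy, sumlogr, n, reml,
                   nullptr, nullptr);
    } else {
      xr = b2; b2 = b1; f2 = f1;
      b1 = xr - gr * (xr - xl);
      f1 = work_ll(b1, d, A, a, G0, g0, yy, sumlogr, n, reml,
                   nullptr, nullptr);
    }
  }
  double lam_hat = 0.5 * (xl + xr);
  double sig2_hat;
  double ll_hat = work_ll(lam_hat, d, A, a, G0, g0, yy, sumlogr, n, reml,
                          &sig2_hat, &out.alpha);

  // the sup includes lam = 0: never report ll_alt below ll_null
  if (ll_hat >= out.ll_null) {
    out.lam = lam_hat;
    out.sigma2 = sig2_hat;
    out.ll_alt = ll_hat;
  } else {
    out.lam = 0.0;
    out.ll_alt = out.ll_null;
    work_ll(0.0, d, A, a, G0, g0, yy, sumlogr, n, reml, &out.sigma2,
            &out.alpha);
  }
  out.tau2 = out.lam * out.sigma2;
  out.boundary = out.lam > 0.999 * upper;
  return out;
}

// Plain logistic IRLS (null model, y on X), used for starting values.
bool irls_logit(const vec& y, const mat& X, double mu_clip, int max_iter,
                double tol, vec& alpha, vec& mu) {
  int p1 = X.n_cols;
  alpha.zeros(p1);
  for (int it = 0; it < max_iter; ++it) {
    vec eta = X * alpha;
    mu = 1.0 / (1.0 + exp(-eta));
    mu = clamp(mu, mu_clip, 1.0 - mu_clip);
    vec v = mu % (1.0 - mu);
    vec z = eta + (y - mu) / v;
    mat Xw = X.each_col() % v;
    vec alpha_new;
    bool ok = solve(alpha_new, X.t() * Xw, X.t() * (v % z), solve_opts::no_approx);
    if (!ok) return false;
    double delta = abs(alpha_new - alpha).max();
    alpha = alpha_new;
    if (delta < tol) {
      vec eta2 = X * alpha;
      mu = clamp(1.0 / (1.0 + exp(-eta2)), mu_clip, 1.0 - mu_clip);
      return true;
    }
  }
  return false;
}

struct PqlOut {
  vec alpha, beta, mu, yw, rdiag;
  double tau2, sigma2, ll_alt, ll_null;
  bool converged, boundary;
  int n_iter;
};

PqlOut pql_core(const vec& y, const mat& X, const mat& Z, const vec& alpha0,
                double tau2_init, double tol, int max_iter, double tau2_upper,
                double mu_clip, int n_grid, bool reml) {
  PqlOut out;
  int K = Z.n_cols;
  vec alpha = alpha0;
  vec beta(K, fill::zeros);
  double tau2 = tau2_init;
  out.converged = false;
  out.boundary = false;
  int iter = 0;

  vec d_f, a_f, g0_f;
  mat A_f, G0_f;
  double yy_f = 0, sumlogr_f = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    vec eta = X * alpha + Z * beta;
    vec mu = clamp(1.0 / (1.0 + exp(-eta)), mu_clip, 1.0 - mu_clip);
    vec v = mu % (1.0 - mu);
    vec rdiag = 1.0 / v;
    vec yw = eta + (y - mu) % rdiag;          // working response Y'
    vec sw = sqrt(v);                          // R^{-1/2} diagonal
    mat Xtil = X.each_col() % sw;
    mat Ztil = Z.each_col() % sw;
    vec ytil = yw % sw;

    mat U, V;
    vec s;
    if (!svd_econ(U, s, V, Ztil))
      Rcpp::stop("SVD of standardized random-effects design failed");
    vec d = s % s;
    mat A = U.t() * Xtil;
    vec a = U.t() * ytil;
    mat G0 = Xtil.t() * Xtil;
    vec g0 = Xtil.t() * ytil;
    double yy = dot(ytil, ytil);
    double sumlogr = -2.0 * accu(log(sw));    // sum log r_i

    // working-model variance fit (REML or ML form, per control)
    WorkOpt w = maximize_tau2(d, A, a, G0, g0, yy, sumlogr, (int)y.n_elem,
                              tau2_upper, n_grid, reml);

    // BLUP: beta = tau2 Z' V^{-1} (Y' - X alpha) = lam Zt' M rtil
    vec rtil = ytil - Xtil * w.alpha;
    vec u = U.t() * rtil;
    vec beta_new = w.lam * (V * (s % (u / (1.0 + w.lam * d))));

    double delta = std::abs(w.tau2 - tau2);
    delta = std::max(delta, abs(w.alpha - alpha).max());
    delta = std::max(delta, abs(beta_new - beta).max());

    alpha = w.alpha;
    beta = beta_new;
    tau2 = w.tau2;
    out.mu = mu;
    out.yw = yw;
    out.rdiag = rdiag;
    out.boundary = w.boundary;
    d_f = d; A_f = A; a_f = a; G0_f = G0; g0_f = g0;
    yy_f = yy; sumlogr_f = sumlogr;

    if (delta < tol) { out.converged = true; break; }
  }
  // The LRT ingredients are always the ML form of the quasi
  // log-likelihood, evaluated on the converged working response and
  // weights: sup over tau2 >= 0 (sigma2 free) and the value at tau2 = 0.
  WorkOpt ml = maximize_tau2(d_f, A_f, a_f, G0_f, g0_f, yy_f, sumlogr_f,
                             (int)y.n_elem, tau2_upper, n_grid, false);
  out.ll_alt = ml.ll_alt;
  out.ll_null = ml.ll_null;
  out.alpha = alpha;
  out.beta = beta;
  out.tau2 = ml.tau2;
  out.sigma2 = ml.sigma2;
  out.n_iter = std::min(iter, max_iter);
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List pql_fit_cpp(const arma::vec& y, const arma::mat& X,
                       const arma::mat& Z, const arma::vec& alpha_init,
                       double tau2_init, double tol, int max_iter,
                       double tau2_upper, double mu_clip, int n_grid,
                       bool reml) {
  PqlOut f = pql_core(y, X, Z, alpha_init, tau2_init, tol, max_iter,
                      tau2_upper, mu_clip, n_grid, reml);
  return Rcpp::List::create(
      Rcpp::Named("alpha_hat") = f.alpha,
      Rcpp::Named("beta_hat") = f.beta,
      Rcpp::Named("tau2_hat") = f.tau2,
      Rcpp::Named("sigma2_hat") = f.sigma2,
      Rcpp::Named("mu") = f.mu,
      Rcpp::Named("working_response") = f.yw,
      Rcpp::Named("r_diag") = f.rdiag,
      Rcpp::Named("loglik_alt") = f.ll_alt,
      Rcpp::Named("loglik_null") = f.ll_null,
      Rcpp::Named("converged") = f.converged,
      Rcpp::Named("boundary") = f.boundary,
      Rcpp::Named("n_iter") = f.n_iter);
}

// Refit the full PQL alternative model on each resampled dataset and
// return the LRT statistics T*_b.  `resample` is B x n: for mode
// "permutation" it holds 1-based row indices applied jointly to (y, X);
// for mode "bootstrap" it holds the redrawn binary responses y*.
// Each replicate is refit from cold start (fresh null-logistic starting
// values), never warm-started from the observed fit.
// [[Rcpp::export]]
Rcpp::List perm_lrt_cpp(const arma::vec& y, const arma::mat& X,
                        const arma::mat& Z, const arma::mat& resample,
                        std::string mode, double tau2_init, double tol,
                        int max_iter, double tau2_upper, double mu_clip,
                        int n_grid, bool reml) {
  int B = resample.n_rows;
  vec T_null(B);
  int n_nonconv = 0;
  bool permute = (mode == "permutation");

  for (int b = 0; b < B; ++b) {
    vec yb;
    mat Xb;
    if (permute) {
      uvec idx = conv_to<uvec>::from(resample.row(b).t()) - 1;
      yb = y.elem(idx);
      Xb = X.rows(idx);
    } else {
      yb = resample.row(b).t();
      Xb = X;
    }
    vec a0, mu0;
    if (!irls_logit(yb, Xb, mu_clip, 50, 1e-8, a0, mu0)) a0.zeros(X.n_cols);
    PqlOut f = pql_core(yb, Xb, Z, a0, tau2_init, tol, max_iter, tau2_upper,
                        mu_clip, n_grid, reml);
    if (!f.converged) ++n_nonconv;
    double T = 2.0 * (f.ll_alt - f.ll_null);
    T_null(b) = (T < 0.0) ? 0.0 : T;
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("T_null") = T_null,
                            Rcpp::Named("n_nonconverged") = n_nonconv);
}
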