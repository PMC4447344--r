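// Fast least-squares / stepwise-selection kernels for Monte-Carlo ensemble
// refitting, plus the joint-acceptance probability accumulator used by the
// grid probability maps.  All model matrices are small (n ~ 15, p <= 10);
// speed comes from avoiding R-level overhead across tens of thousands of
// refits, not from clever linear algebra.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// OLS with intercept-first design matrix X (n x p).  Fills coefficients,
// two-sided t-test p-values (residual df), SSE and the hat-matrix PRESS.
// Returns false on a (numerically) singular cross-product.
static bool ols_core(const mat& X, const vec& y,
                     vec& beta, vec& pval, double& sse, double& press) {
  const int n = X.n_rows, p = X.n_cols;
  mat XtX = X.t() * X;
  mat XtXinv;
  if (!inv_sympd(XtXinv, XtX)) return false;
  beta = XtXinv * (X.t() * y);
  vec resid = y - X * beta;
  sse = dot(resid, resid);
  const int df = n - p;
  pval.set_size(p);
  // a numerically exact interpolation makes t statistics 0/0 garbage:
  // call a clearly non-zero coefficient certain and a zero one pure noise
  const double yscale = std::sqrt(dot(y, y) / n) + 1e-300;
  const bool exact = sse <= 1e-20 * n * yscale * yscale;
  if (df > 0) {
    double s2 = sse / df;
    vec vars = s2 * XtXinv.diag();
    for (int j = 0; j < p; ++j) {
      if (exact || vars[j] <= 0.0) {
        pval[j] = (std::fabs(beta[j]) > 1e-8 * yscale) ? 0.0 : 1.0;
        continue;
      }
      double tstat = beta[j] / std::sqrt(vars[j]);
      pval[j] = 2.0 * R::pt(std::fabs(tstat), (double)df, 0, 0);
    }
  } else {
    pval.fill(NA_REAL);
  }
  // PRESS through leverages: e_i / (1 - h_ii)
  mat HX = X * XtXinv;               // n x p
  press = 0.0;
  for (int i = 0; i < n; ++i) {
    double h = dot(HX.row(i), X.row(i));
    double d = 1.0 - h;
    if (d < 1e-10) { press = NA_REAL; break; }
    double e = resid[i] / d;
    press += e * e;
  }
  return true;
}

// Build [1, C[, included]] with `included` in canonical (ascending) order.
static mat build_X(const mat& C, const std::vector<int>& included) {
  const int n = C.n_rows, k = (int)included.size();
  mat X(n, k + 1);
  X.col(0).ones();
  for (int j = 0; j < k; ++j) X.col(j + 1) = C.col(included[j]);
  return X;
}

// Bidirectional p-value stepwise selection from the intercept-only model.
// Each sweep first adds the candidate with the smallest p-value (if
// p < a_enter; ties broken toward the earlier canonical term), then drops
// the included term with the largest p-value (if p > a_remove; ties broken
// toward the later canonical term).  Status: 0 ok, 1 no convergence within
// max_sweeps, 2 singular fit.
static int stepwise_core(const mat& C, const vec& y,
                         double a_enter, double a_remove, int max_sweeps,
                         std::vector<int>& included,
                         vec& beta_dense, double& sse, double& press,
                         int& ncoef) {
  const int n = C.n_rows, q = C.n_cols;
  included.clear();
  bool converged = false;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    // --- addition step ---
    double best_p = 2.0; int best_j = -1;
    for (int j = 0; j < q; ++j) {
      if (std::find(included.begin(), included.end(), j) != included.end())
        continue;
      if (n - ((int)included.size() + 2) < 1) break;  // keep >= 1 residual df
      std::vector<int> trial(included);
      trial.push_back(j);
      std::sort(trial.begin(), trial.end());
      mat X = build_X(C, trial);
      vec b, pv; double s, pr;
      if (!ols_core(X, y, b, pv, s, pr)) continue;  // collinear: not addable
      int pos = (int)(std::find(trial.begin(), trial.end(), j) - trial.begin()) + 1;
      double pj = pv[pos];
      if (ISNAN(pj)) continue;
      if (pj < best_p) { best_p = pj; best_j = j; }  // strict <: earliest wins ties
    }
    if (best_j >= 0 && best_p < a_enter) {
      included.push_back(best_j);
      std::sort(included.begin(), included.end());
      changed = true;
    }
    // --- removal step ---
    if (!included.empty()) {
      mat X = build_X(C, included);
      vec b, pv; double s, pr;
      if (!ols_core(X, y, b, pv, s, pr)) return 2;
      double worst_p = -1.0; int worst_pos = -1;
      for (int j = 1; j < (int)pv.n_elem; ++j) {
        if (ISNAN(pv[j])) continue;
        if (pv[j] >= worst_p) { worst_p = pv[j]; worst_pos = j; }  // >=: latest wins ties
      }
      if (worst_pos > 0 && worst_p > a_remove) {
        included.erase(included.begin() + (worst_pos - 1));
        changed = true;
      }
    }
    if (!changed) { converged = true; break; }
  }
  // final refit on the selected set
  mat X = build_X(C, included);
  vec b, pv;
  if (!ols_core(X, y, b, pv, sse, press)) return 2;
  beta_dense.zeros(q + 1);
  beta_dense[0] = b[0];
  for (int j = 0; j < (int)included.size(); ++j)
    beta_dense[included[j] + 1] = b[j + 1];
  ncoef = (int)included.size() + 1;
  return converged ? 0 : 1;
}

//' @name cpp_fit_ensemble
//' @keywords internal
// [[Rcpp::export]]
Rcpp::List cpp_fit_ensemble(const arma::mat& C, const arma::mat& Y,
                            double a_enter, double a_remove, int max_sweeps) {
  const int q = C.n_cols, M = Y.n_cols;
  mat coefs(q + 1, M, fill::zeros);
  umat selected(q, M, fill::zeros);
  vec sse(M), press(M);
  Rcpp::IntegerVector ncoef(M), status(M);
  std::vector<int> inc;
  vec bd;
  for (int m = 0; m < M; ++m) {
    double s, pr; int nc;
    int st = stepwise_core(C, Y.col(m), a_enter, a_remove, max_sweeps,
                           inc, bd, s, pr, nc);
    coefs.col(m) = bd;
    for (size_t j = 0; j < inc.size(); ++j) selected(inc[j], m) = 1;
    sse[m] = s; press[m] = pr; ncoef[m] = nc; status[m] = st;
  }
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = coefs,
    Rcpp::Named("selected") = selected,
    Rcpp::Named("sse") = sse,
    Rcpp::Named("press") = press,
    Rcpp::Named("ncoef") = ncoef,
    Rcpp::Named("status") = status);
}

//' @name cpp_joint_prob
//' @keywords internal
// [[Rcpp::export]]
arma::vec cpp_joint_prob(const arma::mat& G, const arma::mat& B, int ncqa,
                         const arma::vec& lower, const arma::vec& upper) {
  const int m = G.n_rows;
  const int nsims = B.n_cols / ncqa;
  vec acc(m, fill::zeros);
  uvec ok(m);
  for (int s = 0; s < nsims; ++s) {
    mat P = G * B.cols(s * ncqa, s * ncqa + ncqa - 1);  // m x ncqa
    ok.ones();
    for (int j = 0; j < ncqa; ++j) {
      const vec pj = P.col(j);
      for (int i = 0; i < m; ++i)
        if (pj[i] < lower[j] || pj[i] > upper[j]) ok[i] = 0;
    }
    for (int i = 0; i < m; ++i) acc[i] += ok[i];
  }
  return acc / (double)nsims;
}
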