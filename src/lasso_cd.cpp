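#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the penalized least-squares objective
//   (1/2n) * sum_i (y_i - sum_j x_ij b_j)^2 + lambda * sum_j pf_j |b_j|
// Columns with pf_j = 0 (intercept-absorbed covariates) are never thresholded.
// X is expected centered; penalized columns scaled to unit 1/n-norm by the
// caller so the coordinate update is a plain soft threshold.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One full sweep over the requested coordinate set; returns max |delta b|.
static double sweep_coords(const NumericMatrix &X, const NumericVector &pf,
                           const NumericVector &xvar, double lambda,
                           std::vector<double> &b, std::vector<double> &r,
                           const std::vector<int> &coords, int n) {
  double maxd = 0.0;
  for (size_t ci = 0; ci < coords.size(); ++ci) {
    int j = coords[ci];
    if (xvar[j] <= 0.0) continue; // constant column: effect pinned at 0
    const double *xj = &X(0, j);
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    rho = rho / n + xvar[j] * b[j];
    double bj = soft(rho, lambda * pf[j]) / xvar[j];
    double d = bj - b[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      b[j] = bj;
      double ad = std::fabs(d);
      if (ad > maxd) maxd = ad;
    }
  }
  return maxd;
}

// [[Rcpp::export]]
List lasso_cd_path(NumericMatrix X, NumericVector y, NumericVector pf,
                   NumericVector lambdas, double tol = 1e-10,
                   int max_iter = 100000, int stop_at_support = -1) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambdas.size();
  NumericVector xvar(p);
  for (int j = 0; j < p; ++j) {
    const double *xj = &X(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xvar[j] = s / n;
  }
  std::vector<double> b(p, 0.0), r(y.begin(), y.end());
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;

  NumericMatrix beta(p, nlam);
  IntegerVector support(nlam);
  int computed = 0;
  for (int l = 0; l < nlam; ++l) {
    double lambda = lambdas[l];
    int iter = 0;
    for (;;) {
      // full sweep (also serves as the KKT check that grows the active set)
      double d0 = sweep_coords(X, pf, xvar, lambda, b, r, all, n);
      if (++iter > max_iter) break;
      if (d0 < tol) break;
      // iterate on the active set until stable
      std::vector<int> act;
      for (int j = 0; j < p; ++j)
        if (b[j] != 0.0) act.push_back(j);
      for (;;) {
        double d1 = sweep_coords(X, pf, xvar, lambda, b, r, act, n);
        if (++iter > max_iter || d1 < tol) break;
      }
      if (iter > max_iter) break;
    }
    int nz = 0;
    for (int j = 0; j < p; ++j) {
      beta(j, l) = b[j];
      if (pf[j] > 0.0 && b[j] != 0.0) ++nz;
    }
    support[l] = nz;
    computed = l + 1;
    if (stop_at_support > 0 && nz >= stop_at_support) break;
  }
  return List::create(_["beta"] = beta, _["support"] = support,
                      _["n_lambda"] = computed);
}
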