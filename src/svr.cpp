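// Epsilon-insensitive support-vector regression, kernel form, solved by
// SMO on the 2n-variable dual (LIBSVM formulation, first-order maximal
// violating pair selection):
//   min 1/2 a'Qa + p'a,  s.t. z'a = 0, 0 <= a <= C,
// with a = (alpha, alpha*), z = (+1...,-1...), Q(s,t) = z_s z_t K(s%n,t%n),
// p = (eps - y, eps + y). Dual coefficients beta = alpha - alpha*; the
// regression function is f(x) = sum_i beta_i K(x_i, x) + b.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct SvrFit {
  std::vector<double> beta;
  double b;
  int iter;
};

// K: row-major contiguous nk x nk kernel of the training points.
static SvrFit svr_smo(const std::vector<double> &K, const std::vector<double> &y,
                      int n, double C, double eps, double tol, int max_iter) {
  const int m = 2 * n;
  std::vector<double> a(m, 0.0), G(m);
  for (int i = 0; i < n; ++i) { G[i] = eps - y[i]; G[n + i] = eps + y[i]; }
  auto zsign = [n](int t) { return t < n ? 1.0 : -1.0; };
  int iter = 0;
  double mval = 0, Mval = 0;
  while (iter < max_iter) {
    // working set: i in I_up maximizing -z G, j in I_low minimizing -z G
    int ii = -1, jj = -1;
    mval = -HUGE_VAL; Mval = HUGE_VAL;
    for (int t = 0; t < m; ++t) {
      double z = zsign(t), v = -z * G[t];
      bool up = (z > 0) ? (a[t] < C) : (a[t] > 0);
      bool low = (z > 0) ? (a[t] > 0) : (a[t] < C);
      if (up && v > mval) { mval = v; ii = t; }
      if (low && v < Mval) { Mval = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || mval - Mval < tol) break;
    int ik = ii % n, jk = jj % n;
    double zi = zsign(ii), zj = zsign(jj);
    double quad = K[ik * n + ik] + K[jk * n + jk] - 2.0 * K[ik * n + jk];
    if (quad <= 1e-12) quad = 1e-12;
    double lam = (mval - Mval) / quad;
    // box: a_ii + zi*lam in [0,C]; a_jj - zj*lam in [0,C]; lam >= 0
    double box_i = (zi > 0) ? (C - a[ii]) : a[ii];
    double box_j = (zj > 0) ? a[jj] : (C - a[jj]);
    if (lam > box_i) lam = box_i;
    if (lam > box_j) lam = box_j;
    if (lam <= 0) break;
    a[ii] += zi * lam;
    a[jj] -= zj * lam;
    // (Q d)_t with d = z_i e_ii - z_j e_jj reduces to z_t (K_ti - K_tj)
    const double *Ki = &K[ik * n], *Kj = &K[jk * n];
    for (int t = 0; t < m; ++t) {
      int tk = t % n;
      G[t] += lam * zsign(t) * (Ki[tk] - Kj[tk]);
    }
    ++iter;
  }
  // intercept from free variables, else midpoint of the KKT bounds
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < m; ++t)
    if (a[t] > 1e-12 && a[t] < C - 1e-12) { bsum += -zsign(t) * G[t]; ++nfree; }
  SvrFit fit;
  fit.b = nfree ? bsum / nfree : 0.5 * (mval + Mval);
  fit.beta.resize(n);
  for (int i = 0; i < n; ++i) fit.beta[i] = a[i] - a[n + i];
  fit.iter = iter;
  return fit;
}

// [[Rcpp::export]]
List svr_train_cpp(NumericMatrix K, NumericVector y, double cost,
                   double epsilon, double tol = 1e-6,
                   int max_iter = 100000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("K must be n x n matching y");
  std::vector<double> Kv(n * n), yv(y.begin(), y.end());
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Kv[i * n + j] = K(i, j);
  SvrFit fit = svr_smo(Kv, yv, n, cost, epsilon, tol, max_iter);
  return List::create(_["beta"] = NumericVector(fit.beta.begin(), fit.beta.end()),
                      _["b"] = fit.b, _["iterations"] = fit.iter);
}

// Leave-one-out predictions given the full-sample kernel matrix.
static void loo_predict(const double *K, const double *y, int n, double C,
                        double eps, double tol, int max_iter, double *pred) {
  std::vector<double> subK((n - 1) * (n - 1)), suby(n - 1);
  std::vector<int> idx(n - 1);
  for (int hold = 0; hold < n; ++hold) {
    int m = 0;
    for (int i = 0; i < n; ++i) if (i != hold) idx[m++] = i;
    for (int i = 0; i < n - 1; ++i) {
      suby[i] = y[idx[i]];
      for (int j = 0; j < n - 1; ++j)
        subK[i * (n - 1) + j] = K[idx[i] * n + idx[j]];
    }
    SvrFit fit = svr_smo(subK, suby, n - 1, C, eps, tol, max_iter);
    double f = fit.b;
    for (int i = 0; i < n - 1; ++i) f += fit.beta[i] * K[hold * n + idx[i]];
    pred[hold] = f;
  }
}

// [[Rcpp::export]]
NumericVector svr_loo_predict_cpp(NumericMatrix K, NumericVector y,
                                  double cost, double epsilon,
                                  double tol = 1e-6, int max_iter = 100000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("K must be n x n matching y");
  std::vector<double> Kv(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Kv[i * n + j] = K(i, j);
  NumericVector pred(n);
  loo_predict(Kv.data(), REAL(y), n, cost, epsilon, tol, max_iter,
              REAL(pred));
  return pred;
}

// R^2 (coefficient of determination) of pooled LOO predictions for each
// row of `perms` (1-based permutations applied to y).
// [[Rcpp::export]]
NumericVector svr_perm_loo_r2_cpp(NumericMatrix K, NumericVector y,
                                  IntegerMatrix perms, double cost,
                                  double epsilon, double tol = 1e-6,
                                  int max_iter = 100000) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("K must be n x n matching y");
  std::vector<double> Kv(n * n), yp(n), pred(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) Kv[i * n + j] = K(i, j);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double sstot = 0.0;
  for (int i = 0; i < n; ++i) sstot += (y[i] - ybar) * (y[i] - ybar);
  int np = perms.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    for (int i = 0; i < n; ++i) yp[i] = y[perms(p, i) - 1];
    loo_predict(Kv.data(), yp.data(), n, cost, epsilon, tol, max_iter,
                pred.data());
    double ssres = 0.0;
    for (int i = 0; i < n; ++i)
      ssres += (yp[i] - pred[i]) * (yp[i] - pred[i]);
    out[p] = 1.0 - ssres / sstot;
    if ((p & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
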