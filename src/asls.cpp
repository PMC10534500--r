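#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric pentadiagonal LDL^T solve: A x = b with A given by its diagonal
// a0 (n), first off-diagonal a1 (n-1) and second off-diagonal a2 (n-2).
// Used for the Whittaker system (W + lambda * D2' D2), which has bandwidth 2.
static void penta_solve(const std::vector<double>& a0,
                        const std::vector<double>& a1,
                        const std::vector<double>& a2,
                        const std::vector<double>& b,
                        std::vector<double>& x,
                        std::vector<double>& d,
                        std::vector<double>& l1,
                        std::vector<double>& l2,
                        std::vector<double>& z) {
  const int n = (int)a0.size();
  for (int i = 0; i < n; ++i) {
    double li2 = 0.0, li1 = 0.0;
    if (i >= 2) li2 = a2[i - 2] / d[i - 2];
    if (i >= 1) {
      double t = a1[i - 1];
      if (i >= 2) t -= li2 * d[i - 2] * l1[i - 1];
      li1 = t / d[i - 1];
    }
    double t = a0[i];
    if (i >= 1) t -= li1 * li1 * d[i - 1];
    if (i >= 2) t -= li2 * li2 * d[i - 2];
    l1[i] = li1;
    l2[i] = li2;
    d[i] = t;
  }
  for (int i = 0; i < n; ++i) {
    double t = b[i];
    if (i >= 1) t -= l1[i] * z[i - 1];
    if (i >= 2) t -= l2[i] * z[i - 2];
    z[i] = t;
  }
  for (int i = 0; i < n; ++i) z[i] /= d[i];
  for (int i = n - 1; i >= 0; --i) {
    double t = z[i];
    if (i + 1 < n) t -= l1[i + 1] * x[i + 1];
    if (i + 2 < n) t -= l2[i + 2] * x[i + 2];
    x[i] = t;
  }
}

// Bands of D2' D2 where D2 is the (n-2) x n second-difference matrix.
static void d2td2_bands(int n, std::vector<double>& a0,
                        std::vector<double>& a1, std::vector<double>& a2) {
  a0.assign(n, 0.0);
  a1.assign(n - 1, 0.0);
  a2.assign(n - 2, 0.0);
  for (int j = 0; j + 2 < n; ++j) {
    a0[j] += 1.0; a0[j + 1] += 4.0; a0[j + 2] += 1.0;
    a1[j] += -2.0; a1[j + 1] += -2.0;
    a2[j] += 1.0;
  }
}

// One asymmetric-least-squares (Eilers) baseline. Weights start at 1 and are
// iteratively reset to p above the current baseline and 1 - p below it.
static int asls_one(const double* y, int n, double lambda, double p,
                    int max_iter, double tol, double* out, bool* converged) {
  std::vector<double> s0, s1, s2;
  d2td2_bands(n, s0, s1, s2);
  for (int i = 0; i < n - 1; ++i) s1[i] *= lambda;
  for (int i = 0; i < n - 2; ++i) s2[i] *= lambda;

  std::vector<double> w(n, 1.0), wprev(n, 1.0), xprev(n, 0.0);
  std::vector<double> a0(n), b(n), x(n), d(n), l1(n), l2(n), z(n);
  double yscale = 1.0;
  for (int i = 0; i < n; ++i) yscale = std::max(yscale, std::fabs(y[i]));
  *converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    for (int i = 0; i < n; ++i) a0[i] = w[i] + lambda * s0[i];
    for (int i = 0; i < n; ++i) b[i] = w[i] * y[i];
    penta_solve(a0, s1, s2, b, x, d, l1, l2, z);
    double maxchg = 0.0, basechg = 0.0;
    for (int i = 0; i < n; ++i) {
      wprev[i] = w[i];
      w[i] = (y[i] > x[i]) ? p : 1.0 - p;
      double c = std::fabs(w[i] - wprev[i]);
      if (c > maxchg) maxchg = c;
      c = std::fabs(x[i] - xprev[i]);
      if (c > basechg) basechg = c;
      xprev[i] = x[i];
    }
    // Converged when the weights settle, or when the baseline itself stops
    // moving (weight oscillation on near-tie points does not matter then).
    if (it > 1 && (maxchg < tol || basechg < tol * yscale)) {
      *converged = true;
      break;
    }
  }
  for (int i = 0; i < n; ++i) out[i] = x[i];
  return it > max_iter ? max_iter : it;
}

// [[Rcpp::export]]
List asls_baseline_cpp(NumericVector y, double lambda, double p,
                       int max_iter, double tol) {
  const int n = y.size();
  NumericVector base(n);
  bool conv = false;
  int it = asls_one(REAL(y), n, lambda, p, max_iter, tol, REAL(base), &conv);
  return List::create(_["baseline"] = base, _["iterations"] = it,
                      _["converged"] = conv);
}

// Column-wise AsLS baselines for a matrix of spectra (bands x nspectra).
// [[Rcpp::export]]
List asls_baseline_matrix_cpp(NumericMatrix Y, double lambda, double p,
                              int max_iter, double tol) {
  const int n = Y.nrow(), m = Y.ncol();
  NumericMatrix base(n, m);
  LogicalVector conv(m);
  IntegerVector iters(m);
  for (int j = 0; j < m; ++j) {
    bool c = false;
    iters[j] = asls_one(&Y(0, j), n, lambda, p, max_iter, tol, &base(0, j), &c);
    conv[j] = c;
  }
  return List::create(_["baseline"] = base, _["iterations"] = iters,
                      _["converged"] = conv);
}
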