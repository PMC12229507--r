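#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric least squares baseline (Whittaker smoother with asymmetric
// weights). The normal equations (W + lambda * D'D) z = W y, with D the
// second-difference operator, are pentadiagonal SPD for lambda > 0; they
// are factored by a banded LDL^T recurrence in O(n) per iteration.

namespace {

struct PentaLDL {
  std::vector<double> D, l1, l2;
  void factor(const std::vector<double>& d, const std::vector<double>& e,
              const std::vector<double>& f) {
    const int n = d.size();
    D.assign(n, 0.0);
    l1.assign(n > 1 ? n - 1 : 0, 0.0);
    l2.assign(n > 2 ? n - 2 : 0, 0.0);
    D[0] = d[0];
    if (n > 1) {
      l1[0] = e[0] / D[0];
      if (n > 2) l2[0] = f[0] / D[0];
      D[1] = d[1] - l1[0] * l1[0] * D[0];
      if (n > 2) l1[1] = (e[1] - l2[0] * l1[0] * D[0]) / D[1];
      if (n > 3) l2[1] = f[1] / D[1];
    }
    for (int i = 2; i < n; ++i) {
      D[i] = d[i] - l1[i - 1] * l1[i - 1] * D[i - 1] -
             l2[i - 2] * l2[i - 2] * D[i - 2];
      if (i <= n - 2)
        l1[i] = (e[i] - l2[i - 1] * l1[i - 1] * D[i - 1]) / D[i];
      if (i <= n - 3) l2[i] = f[i] / D[i];
    }
  }
  void solve(const std::vector<double>& b, std::vector<double>& z) const {
    const int n = b.size();
    std::vector<double> v(n);
    v[0] = b[0];
    if (n > 1) v[1] = b[1] - l1[0] * v[0];
    for (int i = 2; i < n; ++i)
      v[i] = b[i] - l1[i - 1] * v[i - 1] - l2[i - 2] * v[i - 2];
    for (int i = 0; i < n; ++i) v[i] /= D[i];
    z.assign(n, 0.0);
    z[n - 1] = v[n - 1];
    if (n > 1) z[n - 2] = v[n - 2] - l1[n - 2] * z[n - 1];
    for (int i = n - 3; i >= 0; --i)
      z[i] = v[i] - l1[i] * z[i + 1] - l2[i] * z[i + 2];
  }
};

// Bands of lambda * D'D for the (n-2) x n second-difference matrix.
void penalty_bands(int n, double lam, std::vector<double>& c,
                   std::vector<double>& e, std::vector<double>& f) {
  c.assign(n, 6.0 * lam);
  c[0] = c[n - 1] = 1.0 * lam;
  if (n > 1) c[1] = c[n - 2] = (n > 3 ? 5.0 : 1.0) * lam;
  e.assign(n - 1, -4.0 * lam);
  e[0] = e[n - 2] = -2.0 * lam;
  f.assign(n - 2, 1.0 * lam);
}

// pentadiagonal matvec r = A x for A with bands (d, e, f)
static void penta_mult(const std::vector<double>& d,
                       const std::vector<double>& e,
                       const std::vector<double>& f,
                       const std::vector<double>& x, std::vector<double>& r) {
  const int n = d.size();
  for (int i = 0; i < n; ++i) {
    double v = d[i] * x[i];
    if (i > 0) v += e[i - 1] * x[i - 1];
    if (i < n - 1) v += e[i] * x[i + 1];
    if (i > 1) v += f[i - 2] * x[i - 2];
    if (i < n - 2) v += f[i] * x[i + 2];
    r[i] = v;
  }
}

int asls_one(const double* y, int n, double lam, double p, int max_iter,
             double tol, double* zout) {
  std::vector<double> pc, pe, pf;
  penalty_bands(n, lam, pc, pe, pf);
  std::vector<double> w(n, 1.0), d(n), b(n), z(n), r(n), dz(n);
  PentaLDL ldl;
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    ++iters;
    for (int i = 0; i < n; ++i) {
      d[i] = w[i] + pc[i];
      b[i] = w[i] * y[i];
    }
    // off-diagonals are pure penalty terms; W only touches the diagonal
    ldl.factor(d, pe, pf);
    ldl.solve(b, z);
    // one step of iterative refinement (the system is ill-conditioned for
    // large lambda / small asymmetry weights)
    penta_mult(d, pe, pf, z, r);
    for (int i = 0; i < n; ++i) r[i] = b[i] - r[i];
    ldl.solve(r, dz);
    for (int i = 0; i < n; ++i) z[i] += dz[i];
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double wn = (y[i] > z[i]) ? p : 1.0 - p;
      delta = std::max(delta, std::fabs(wn - w[i]));
      w[i] = wn;
    }
    if (delta <= tol) break;
  }
  std::copy(z.begin(), z.end(), zout);
  return iters;
}

}  // namespace

// [[Rcpp::export(name = ".asls_baseline_cpp")]]
List asls_baseline_cpp(NumericVector y, double lam, double p, int max_iter,
                       double tol) {
  const int n = y.size();
  if (n < 4) stop("asls baseline needs at least 4 channels");
  NumericVector z(n);
  int iters = asls_one(REAL(y), n, lam, p, max_iter, tol, REAL(z));
  return List::create(_["baseline"] = z, _["iterations"] = iters);
}

// [[Rcpp::export(name = ".asls_baseline_mat_cpp")]]
List asls_baseline_mat_cpp(NumericMatrix Y, double lam, double p,
                           int max_iter, double tol) {
  const int n = Y.nrow(), m = Y.ncol();
  if (n < 4) stop("asls baseline needs at least 4 channels");
  NumericMatrix Z(n, m);
  IntegerVector iters(m);
  for (int j = 0; j < m; ++j)
    iters[j] = asls_one(&Y(0, j), n, lam, p, max_iter, tol, &Z(0, j));
  return List::create(_["baseline"] = Z, _["iterations"] = iters);
}
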