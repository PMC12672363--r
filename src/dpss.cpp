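#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete prolate spheroidal sequences via the symmetric tridiagonal
// eigenproblem (Percival & Walden formulation): diagonal
// ((N-1-2t)/2)^2 cos(2*pi*W), off-diagonal t(N-t)/2. The K slepians are the
// eigenvectors belonging to the K largest eigenvalues, found by Sturm-count
// bisection followed by inverse iteration with a partially pivoted
// tridiagonal solve. Columns are unit-norm.

static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e2, double x) {
  // number of eigenvalues strictly less than x
  int n = d.size(), cnt = 0;
  double q = d[0] - x;
  if (q < 0) ++cnt;
  for (int i = 1; i < n; ++i) {
    if (q == 0.0) q = 1e-300;
    q = d[i] - x - e2[i] / q;
    if (q < 0) ++cnt;
  }
  return cnt;
}

static void tridiag_solve_pivot(std::vector<double> a, std::vector<double> b,
                                std::vector<double> c, std::vector<double>& x) {
  // solves T x = rhs in-place where T has sub/sup-diagonal a/c and diagonal b;
  // Gaussian elimination with partial pivoting (one extra superdiagonal fill-in)
  int n = b.size();
  std::vector<double> d(n, 0.0);       // second superdiagonal fill-in
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(a[i + 1]) > std::fabs(b[i])) {
      std::swap(b[i], a[i + 1]);
      std::swap(c[i], b[i + 1]);
      double tmp = d[i]; d[i] = c[i + 1]; c[i + 1] = tmp;
      std::swap(x[i], x[i + 1]);
    }
    if (b[i] == 0.0) b[i] = 1e-300;
    double m = a[i + 1] / b[i];
    b[i + 1] -= m * c[i];
    c[i + 1] -= m * d[i];
    x[i + 1] -= m * x[i];
  }
  if (b[n - 1] == 0.0) b[n - 1] = 1e-300;
  x[n - 1] /= b[n - 1];
  if (n >= 2) x[n - 2] = (x[n - 2] - c[n - 2] * x[n - 1]) / b[n - 2];
  for (int i = n - 3; i >= 0; --i)
    x[i] = (x[i] - c[i] * x[i + 1] - d[i] * x[i + 2]) / b[i];
}

// [[Rcpp::export]]
NumericMatrix dpss_tapers_cpp(int n, double nw, int k) {
  if (n < 2 || k < 1 || k > n) stop("invalid taper request");
  double W = nw / n;
  double ct = std::cos(2.0 * M_PI * W);
  std::vector<double> diag(n), off(n, 0.0), off2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double h = (n - 1.0 - 2.0 * i) / 2.0;
    diag[i] = h * h * ct;
  }
  for (int i = 1; i < n; ++i) {
    off[i] = i * (n - (double)i) / 2.0;    // element coupling i-1 and i
    off2[i] = off[i] * off[i];
  }
  // Gershgorin bounds
  double lo = diag[0], hi = diag[0];
  for (int i = 0; i < n; ++i) {
    double r = (i > 0 ? std::fabs(off[i]) : 0.0) +
               (i < n - 1 ? std::fabs(off[i + 1]) : 0.0);
    lo = std::min(lo, diag[i] - r);
    hi = std::max(hi, diag[i] + r);
  }
  NumericMatrix out(n, k);
  std::vector<std::vector<double>> found;
  for (int j = 0; j < k; ++j) {
    // eigenvalue with exactly n-1-j eigenvalues strictly below it
    int want = n - 1 - j;
    double a = lo, b = hi;
    for (int it = 0; it < 100 && (b - a) > 1e-10 * std::max(1.0, std::fabs(b)); ++it) {
      double m = 0.5 * (a + b);
      if (sturm_count(diag, off2, m) <= want) a = m; else b = m;
    }
    double lambda = 0.5 * (a + b);
    // inverse iteration
    std::vector<double> v(n), shifted(n);
    for (int i = 0; i < n; ++i) v[i] = 1.0 / std::sqrt((double)n) * (1.0 + 0.5 * std::sin(2.0 * M_PI * (i + 1.0) * (j + 1.0) / n));
    for (int iter = 0; iter < 6; ++iter) {
      for (int i = 0; i < n; ++i) shifted[i] = diag[i] - lambda;
      std::vector<double> sub(off), sup(off);
      // sub[i] couples rows i-1,i ; represent sub-diag as a[1..n-1], sup as c[0..n-2]
      std::vector<double> a2(n, 0.0), c2(n, 0.0);
      for (int i = 1; i < n; ++i) a2[i] = off[i];
      for (int i = 0; i < n - 1; ++i) c2[i] = off[i + 1];
      tridiag_solve_pivot(a2, shifted, c2, v);
      // orthogonalize against previously found vectors
      for (size_t f = 0; f < found.size(); ++f) {
        double dot = 0;
        for (int i = 0; i < n; ++i) dot += v[i] * found[f][i];
        for (int i = 0; i < n; ++i) v[i] -= dot * found[f][i];
      }
      double nrm = 0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      if (nrm == 0) stop("inverse iteration failed");
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    // polarity convention: positive mean for symmetric tapers, positive
    // initial slope for antisymmetric ones (cosmetic only)
    double s = 0;
    for (int i = 0; i < n; ++i) s += v[i];
    if (std::fabs(s) < 1e-6) { if (v[1] - v[0] < 0) for (int i = 0; i < n; ++i) v[i] = -v[i]; }
    else if (s < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    for (int i = 0; i < n; ++i) out(i, j) = v[i];
    found.push_back(v);
  }
  return out;
}
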