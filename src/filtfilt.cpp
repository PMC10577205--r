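#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zero-phase IIR filtering down the columns of a (time x series) matrix.
//
// Each column is extended at both ends by an odd reflection of length
// 3 * (ncoef - 1), filtered forward and backward in direct form II
// transposed, with the filter state initialised to the unit-step steady
// state scaled by the first sample. A constant input therefore maps to
// its steady-state response (zero for a high-pass) with no edge transient,
// and the forward-backward pass cancels the phase response so peak
// latencies are not shifted.

// Steady-state DF2T state for a unit step input (solve (I - A^T) zi = B
// with A the companion matrix of a). Small dense Gaussian elimination;
// m is at most the filter order (<= 8 here).
static std::vector<double> step_zi(const std::vector<double>& b,
                                   const std::vector<double>& a) {
  const int m = (int)a.size() - 1;
  std::vector<double> M(m * m, 0.0), rhs(m);
  for (int i = 0; i < m; ++i) {
    rhs[i] = b[i + 1] - a[i + 1] * b[0];
    for (int j = 0; j < m; ++j) {
      // A^T[i][j]: companion(a) has first row -a[1..m], subdiagonal ones
      double at = (j == 0) ? -a[i + 1] : ((j == i + 1) ? 1.0 : 0.0);
      M[i * m + j] = ((i == j) ? 1.0 : 0.0) - at;
    }
  }
  // partial-pivot elimination
  std::vector<int> piv(m);
  for (int i = 0; i < m; ++i) piv[i] = i;
  for (int c = 0; c < m; ++c) {
    int best = c;
    for (int r = c + 1; r < m; ++r)
      if (std::abs(M[r * m + c]) > std::abs(M[best * m + c])) best = r;
    if (best != c) {
      for (int j = 0; j < m; ++j) std::swap(M[c * m + j], M[best * m + j]);
      std::swap(rhs[c], rhs[best]);
    }
    double d = M[c * m + c];
    for (int r = c + 1; r < m; ++r) {
      double f = M[r * m + c] / d;
      for (int j = c; j < m; ++j) M[r * m + j] -= f * M[c * m + j];
      rhs[r] -= f * rhs[c];
    }
  }
  std::vector<double> zi(m);
  for (int r = m - 1; r >= 0; --r) {
    double s = rhs[r];
    for (int j = r + 1; j < m; ++j) s -= M[r * m + j] * zi[j];
    zi[r] = s / M[r * m + r];
  }
  return zi;
}

// One lfilter pass, DF2T, in place on x[0..n). The state starts at the
// steady state for a constant input x0 (the local mean level at the edge,
// not the single edge sample: an oscillating signal would otherwise
// inject a slow transient scaled by the arbitrary edge value).
static void lfilter(const std::vector<double>& b, const std::vector<double>& a,
                    const std::vector<double>& zi_unit, double* x, int n,
                    double x0) {
  const int m = (int)a.size() - 1;
  if (m == 4) {  // fast path for the 4th-order stages used throughout
    const double b0 = b[0], b1 = b[1], b2 = b[2], b3 = b[3], b4 = b[4];
    const double a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4];
    double z0 = zi_unit[0] * x0, z1 = zi_unit[1] * x0,
           z2 = zi_unit[2] * x0, z3 = zi_unit[3] * x0;
    for (int t = 0; t < n; ++t) {
      const double xt = x[t];
      const double y = b0 * xt + z0;
      z0 = b1 * xt + z1 - a1 * y;
      z1 = b2 * xt + z2 - a2 * y;
      z2 = b3 * xt + z3 - a3 * y;
      z3 = b4 * xt - a4 * y;
      x[t] = y;
    }
    return;
  }
  std::vector<double> z(m);
  for (int k = 0; k < m; ++k) z[k] = zi_unit[k] * x0;
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double y = b[0] * xt + z[0];
    for (int k = 0; k < m - 1; ++k) z[k] = b[k + 1] * xt + z[k + 1] - a[k + 1] * y;
    z[m - 1] = b[m] * xt - a[m] * y;
    x[t] = y;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_cols(NumericVector b_, NumericVector a_, NumericMatrix X,
                                int padlen = -1) {
  int nb = b_.size(), na = a_.size();
  int nc = std::max(na, nb);
  std::vector<double> b(nc, 0.0), a(nc, 0.0);
  for (int i = 0; i < nb; ++i) b[i] = b_[i];
  for (int i = 0; i < na; ++i) a[i] = a_[i];
  if (a[0] == 0.0) stop("a[1] must be non-zero");
  for (int i = nc - 1; i >= 0; --i) { b[i] /= a[0]; a[i] /= a[0]; }

  const int n = X.nrow(), ncol = X.ncol();
  const int pad = (padlen >= 0) ? std::min(padlen, n - 1) : 3 * (nc - 1);
  if (n <= pad) stop("signal too short for filtfilt padding (need > %d samples)", pad);
  std::vector<double> zi = step_zi(b, a);
  NumericMatrix out(n, ncol);
  const int ne = n + 2 * pad;
  std::vector<double> ext(ne);
  // Even (mirror) reflection: unlike odd reflection it adds no level shift
  // at the edges, which matters for a high-pass whose time constant is
  // comparable to the pad length.
  const int win = std::min(n, 100);  // edge window for the local mean level
  for (int j = 0; j < ncol; ++j) {
    const double* col = &X(0, j);
    for (int i = 0; i < pad; ++i) ext[i] = col[pad - i];
    for (int i = 0; i < n; ++i) ext[pad + i] = col[i];
    for (int i = 0; i < pad; ++i) ext[pad + n + i] = col[n - 2 - i];
    double head = 0.0;
    for (int i = 0; i < win; ++i) head += col[i];
    head /= win;
    lfilter(b, a, zi, ext.data(), ne, head);
    double tail = 0.0;  // local mean at the end of the forward-filtered trace
    for (int i = 0; i < win; ++i) tail += ext[ne - 1 - i];
    tail /= win;
    std::reverse(ext.begin(), ext.end());
    lfilter(b, a, zi, ext.data(), ne, tail);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < n; ++i) out(i, j) = ext[pad + i];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col_p2p(NumericMatrix X) {
  const int n = X.nrow(), m = X.ncol();
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double* col = &X(0, j);
    double lo = col[0], hi = col[0];
    for (int i = 1; i < n; ++i) {
      if (col[i] < lo) lo = col[i];
      else if (col[i] > hi) hi = col[i];
    }
    out[j] = hi - lo;
  }
  return out;
}
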