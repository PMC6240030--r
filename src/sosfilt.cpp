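#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed.
// sos: one row per section, columns b0 b1 b2 a0 a1 a2 (a0 == 1).
// Zero initial conditions; callers handle zero-phase composition.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericVector x, NumericMatrix sos) {
  const int n = x.size();
  const int ns = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = 0.0, w2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

static void sos_pass(std::vector<double>& y, const NumericMatrix& sos) {
  const int n = (int)y.size();
  const int ns = sos.nrow();
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double w1 = 0.0, w2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + w1;
      w1 = b1 * xi - a1 * yi + w2;
      w2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
}

// Zero-phase SOS filtering, symmetric under time reversal: average of the
// forward-then-backward and backward-then-forward compositions, computed on
// an odd-reflection padded copy of the signal. `pad` is the reflection
// length in samples.
// [[Rcpp::export]]
NumericVector sosfiltfilt_cpp(NumericVector x, NumericMatrix sos, int pad) {
  const int n = x.size();
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  const int m = n + 2 * pad;
  std::vector<double> xp(m);
  for (int i = 0; i < pad; ++i) xp[i] = 2.0 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) xp[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) xp[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];

  std::vector<double> a(xp), b(xp);
  // a = rev(F(rev(F(xp))))
  sos_pass(a, sos);
  std::reverse(a.begin(), a.end());
  sos_pass(a, sos);
  std::reverse(a.begin(), a.end());
  // b = F(rev(F(rev(xp))))
  std::reverse(b.begin(), b.end());
  sos_pass(b, sos);
  std::reverse(b.begin(), b.end());
  sos_pass(b, sos);

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 0.5 * (a[pad + i] + b[pad + i]);
  return out;
}

// Add scaled copies of a short template at given 0-based sample offsets.
// Used by the simulator to place thousands of spike transients quickly.
// [[Rcpp::export]]
NumericVector add_events_cpp(NumericVector x, NumericVector tmpl,
                             IntegerVector at, NumericVector amp) {
  const int n = x.size(), L = tmpl.size(), m = at.size();
  NumericVector y = clone(x);
  for (int k = 0; k < m; ++k) {
    const int i0 = at[k];
    const double a = amp[k];
    for (int j = 0; j < L; ++j) {
      const int i = i0 + j;
      if (i >= 0 && i < n) y[i] += a * tmpl[j];
    }
  }
  return y;
}
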