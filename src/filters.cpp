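#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR/FIR filter, zero initial conditions
// (the convention of scipy.signal.lfilter); a[0] must be 1.
// [[Rcpp::export(name = ".arma_filter")]]
NumericVector arma_filter(NumericVector x, NumericVector b, NumericVector a) {
  const int n = x.size();
  const int nb = b.size();
  const int na = a.size();
  const int nz = std::max(nb, na) - 1;
  if (na < 1 || a[0] != 1.0) stop("a[0] must be 1");
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0), z(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const double* bp = bb.data();
  const double* ap = aa.data();
  double* zp = z.data();  // z[nz] stays 0 as a sentinel
  for (int i = 0; i < n; ++i) {
    const double xi = xp[i];
    const double yi = bp[0] * xi + zp[0];
    for (int j = 1; j <= nz; ++j)
      zp[j - 1] = bp[j] * xi + zp[j] - ap[j] * yi;
    yp[i] = yi;
  }
  return y;
}

// Superpose a waveform at multiple onset sample indices (1-based) with
// per-event gains; returns a modified copy of the voltage series.
// [[Rcpp::export(name = ".add_events")]]
NumericVector add_events(NumericVector v, NumericVector wave,
                         IntegerVector onsets, NumericVector gains) {
  NumericVector out = clone(v);
  const int n = out.size();
  const int L = wave.size();
  double* op = REAL(out);
  const double* wp = REAL(wave);
  for (int e = 0; e < onsets.size(); ++e) {
    const int i0 = onsets[e] - 1;
    const double g = gains[e];
    const int m = std::min(L, n - i0);
    for (int j = 0; j < m; ++j) op[i0 + j] += g * wp[j];
  }
  return out;
}
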