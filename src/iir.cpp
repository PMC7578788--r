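#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions zi
// (scaled by the caller). a[0] must be 1. Used by the zero-phase
// filter chain; the loop is the hot path at session lengths (~1e6
// samples), hence compiled.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  const int n = x.size();
  const int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int m = 0; m < n; ++m) {
    const double xm = x[m];
    const double ym = bb[0] * xm + z[0];
    for (int i = 0; i < nf - 2; ++i)
      z[i] = bb[i + 1] * xm + z[i + 1] - aa[i + 1] * ym;
    z[nf - 2] = bb[nf - 1] * xm - aa[nf - 1] * ym;
    y[m] = ym;
  }
  return y;
}
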