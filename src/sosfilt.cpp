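#include <Rcpp.h>
using namespace Rcpp;

// Cascaded biquad filtering (direct form II transposed), one column per
// channel. sos is n_sections x 6: b0 b1 b2 a0(=1) a1 a2. Zero initial state;
// callers are expected to pad the signal themselves. Raw column pointers:
// the recursion is latency-bound, so accessor overhead would dominate.
// [[Rcpp::export]]
NumericMatrix sosfilt_cpp(NumericMatrix x, NumericMatrix sos) {
  const int n = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  NumericMatrix y(clone(x));
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    b0[s] = sos(s, 0); b1[s] = sos(s, 1); b2[s] = sos(s, 2);
    a1[s] = sos(s, 4); a2[s] = sos(s, 5);
  }
  for (int c = 0; c < nc; ++c) {
    double* col = &y(0, c);
    for (int s = 0; s < ns; ++s) {
      const double B0 = b0[s], B1 = b1[s], B2 = b2[s];
      const double A1 = a1[s], A2 = a2[s];
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xi = col[i];
        const double yi = B0 * xi + z1;
        z1 = B1 * xi - A1 * yi + z2;
        z2 = B2 * xi - A2 * yi;
        col[i] = yi;
      }
    }
  }
  return y;
}
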