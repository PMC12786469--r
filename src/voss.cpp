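#include <Rcpp.h>
using namespace Rcpp;

// Voss-McCartney row expansion: draws holds the concatenated white rows
// (row 0: n values updated every sample; row k: ceil(n / 2^k) values
// each held for 2^k samples). Returns the per-sample sum.
// [[Rcpp::export(name = ".vossExpand")]]
NumericVector voss_expand(NumericVector draws, R_xlen_t n, int nRows) {
  NumericVector acc(n);
  double *a = acc.begin();
  const double *dr = draws.begin();
  R_xlen_t off = 0;
  for (int k = 0; k < nRows; ++k) {
    const R_xlen_t hold = (R_xlen_t)1 << k;
    const R_xlen_t m = (n + hold - 1) / hold;
    if (off + m > draws.size()) stop("draw buffer too short");
    for (R_xlen_t b = 0; b < m; ++b) {
      const double v = dr[off + b];
      const R_xlen_t lo = b * hold;
      const R_xlen_t hi = std::min(lo + hold, n);
      for (R_xlen_t i = lo; i < hi; ++i) a[i] += v;
    }
    off += m;
  }
  return acc;
}
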