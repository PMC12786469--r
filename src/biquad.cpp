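#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Time-varying RBJ band-pass biquad (constant 0 dB peak gain), direct
// form II transposed. Center frequency is fixed; Q is a per-sample
// automation track, so the coefficients are recomputed every sample.
// [[Rcpp::export(name = ".biquadBandpassTV")]]
NumericVector biquad_bandpass_tv(NumericVector x, double f0,
                                 NumericVector Q, double fs) {
  const R_xlen_t n = x.size();
  if (Q.size() != n) stop("Q track must match the signal length");
  NumericVector y(n);
  const double w0 = 2.0 * M_PI * f0 / fs;
  const double cw = std::cos(w0), sw = std::sin(w0);
  double z1 = 0.0, z2 = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double q = Q[i] > 1e-6 ? Q[i] : 1e-6;
    const double alpha = sw / (2.0 * q);
    const double a0 = 1.0 + alpha;
    const double b0 = alpha / a0;
    const double b2 = -alpha / a0;
    const double a1 = -2.0 * cw / a0;
    const double a2 = (1.0 - alpha) / a0;
    const double xi = x[i];
    const double yi = b0 * xi + z1;
    z1 = -a1 * yi + z2;            // b1 = 0
    z2 = b2 * xi - a2 * yi;
    y[i] = yi;
  }
  return y;
}
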