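#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// iterative radix-2 complex FFT (in place); n must be a power of two
static void fft_radix2(std::vector<double> &re, std::vector<double> &im,
                       const std::vector<double> &ctab,
                       const std::vector<double> &stab) {
  const size_t n = re.size();
  // bit-reversal permutation
  for (size_t i = 1, j = 0; i < n; ++i) {
    size_t bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) { std::swap(re[i], re[j]); std::swap(im[i], im[j]); }
  }
  for (size_t len = 2; len <= n; len <<= 1) {
    const size_t stride = n / len;
    for (size_t i = 0; i < n; i += len) {
      for (size_t k = 0; k < len / 2; ++k) {
        const double wr = ctab[k * stride], wi = stab[k * stride];
        const size_t a = i + k, b = i + k + len / 2;
        const double tr = re[b] * wr - im[b] * wi;
        const double ti = re[b] * wi + im[b] * wr;
        re[b] = re[a] - tr; im[b] = im[a] - ti;
        re[a] += tr;        im[a] += ti;
      }
    }
  }
}

// One STFT pass over a mono signal (Hann window): pooled power spectrum,
// frame-averaged spectral centroid and the frame RMS envelope.
// frame must be a power of two.
// [[Rcpp::export(name = ".stftStatsCore")]]
List stft_stats_core(NumericVector x, double fs, int frame, int hop) {
  const R_xlen_t n = x.size();
  if (n < frame) stop("audio shorter than one analysis frame");
  if (frame & (frame - 1)) stop("frame length must be a power of two");
  const R_xlen_t nFrames = (n - frame) / hop + 1;
  const int nb = frame / 2 + 1;

  std::vector<double> w(frame), ctab(frame / 2), stab(frame / 2);
  for (int i = 0; i < frame; ++i)
    w[i] = 0.5 - 0.5 * std::cos(2.0 * M_PI * (i + 1.0) / frame);
  for (int k = 0; k < frame / 2; ++k) {
    ctab[k] = std::cos(-2.0 * M_PI * k / frame);
    stab[k] = std::sin(-2.0 * M_PI * k / frame);
  }

  NumericVector poolPower(nb), rmsEnv(nFrames), freqs(nb);
  for (int k = 0; k < nb; ++k) freqs[k] = k * fs / frame;
  double centSum = 0.0;
  R_xlen_t centN = 0;
  std::vector<double> re(frame), im(frame);

  for (R_xlen_t f = 0; f < nFrames; ++f) {
    const double *seg = &x[f * hop];
    double ss = 0.0;
    for (int i = 0; i < frame; ++i) {
      ss += seg[i] * seg[i];
      re[i] = seg[i] * w[i];
      im[i] = 0.0;
    }
    rmsEnv[f] = std::sqrt(ss / frame);
    fft_radix2(re, im, ctab, stab);
    double msum = 0.0, fsum = 0.0;
    for (int k = 0; k < nb; ++k) {
      const double p = re[k] * re[k] + im[k] * im[k];
      poolPower[k] += p;
      const double mag = std::sqrt(p);
      msum += mag;
      fsum += freqs[k] * mag;
    }
    if (msum > 1e-12) { centSum += fsum / msum; ++centN; }
  }
  return List::create(
    _["freqs"] = freqs, _["poolPower"] = poolPower,
    _["centroid"] = centN > 0 ? centSum / centN : NA_REAL,
    _["rmsEnv"] = rmsEnv);
}
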