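#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-pass regional synthesis chain. Semantically identical to composing
// the package's R operators (oscSine, oscTriangle, applyTremolo,
// bitcrush, crossfade, rampTrack, the 2nd-order high-passes and the
// time-varying regional band-pass); a unit test asserts the equivalence.
//
// paramTargets columns (one row per window):
//  0 fDelta  1 fTheta  2 fAlphaEffective (detune pre-applied)
//  3 unused  4 tremRateBeta
//  5 tremRateGamma  6 tremDepthBeta  7 tremDepthGamma
//  8 gDelta  9 gTheta 10 gAlpha 11 gBeta 12 gGamma 13 qFactor 14 fade
// pink/white are unit-SD noise sample vectors (pre-filter).
// hpb*/hpa* are the 2nd-order Butterworth high-pass coefficients
// (b of length 3, a of length 3 with a[0] = 1).
// [[Rcpp::export(name = ".renderRegionCore")]]
NumericVector render_region_core(NumericMatrix paramTargets, double stepS,
                                 double rampS, double fs,
                                 NumericVector pink, NumericVector white,
                                 NumericVector hpbB, NumericVector hpaB,
                                 NumericVector hpbG, NumericVector hpaG,
                                 double bpCenter, double qBase,
                                 double qSpan, int bits) {
  const int W = paramTargets.nrow();
  const int nStep = (int)std::lround(stepS * fs);
  const R_xlen_t n = (R_xlen_t)W * nStep;
  if (pink.size() < n || white.size() < n)
    stop("noise buffers shorter than the render length");
  NumericVector y(n);

  // decay per sample for the exponential-approach ramps:
  //   state -> target + (state - target) * exp(-1 / (fs * tau)),
  // tau = rampS / ln(100)
  const double d = std::exp(-std::log(100.0) / (fs * rampS));

  const int NP = 15;
  double st[NP];
  for (int p = 0; p < NP; ++p) st[p] = paramTargets(0, p);

  // oscillator / tremolo phase accumulators (radians except alpha cycle)
  double phD = 0.0, phT = 0.0, cycA = 0.0, phTB = 0.0, phTG = 0.0;
  const double twopi = 2.0 * M_PI;

  // high-pass biquad states (DF2T)
  double zb1 = 0.0, zb2 = 0.0, zg1 = 0.0, zg2 = 0.0;
  // regional band-pass state
  double zr1 = 0.0, zr2 = 0.0;
  const double w0 = twopi * bpCenter / fs;
  const double cw = std::cos(w0), sw = std::sin(w0);
  const double q16 = std::pow(2.0, bits - 1);

  for (R_xlen_t i = 0; i < n; ++i) {
    const int win = (int)(i / nStep);
    for (int p = 0; p < NP; ++p) {
      const double tgt = paramTargets(win, p);
      st[p] = tgt + (st[p] - tgt) * d;
    }
    // phase-continuous oscillators; the first sample sits at phase 0
    if (i > 0) {
      phD += twopi * st[0] / fs;
      phT += twopi * st[1] / fs;
      cycA += st[2] / fs;
      cycA -= std::floor(cycA);
      phTB += twopi * st[4] / fs;
      phTG += twopi * st[5] / fs;
    }
    const double delta = std::sin(phD);
    const double theta = std::sin(phT);
    const double alpha = 4.0 * std::fabs(cycA - 0.5) - 1.0;

    // beta: pink -> HP(600) -> tremolo
    double xb = pink[i];
    double yb = hpbB[0] * xb + zb1;
    zb1 = hpbB[1] * xb - hpaB[1] * yb + zb2;
    zb2 = hpbB[2] * xb - hpaB[2] * yb;
    yb *= 1.0 - st[6] * (1.0 + std::sin(phTB)) / 2.0;

    // gamma: white -> HP(2000) -> tremolo
    double xg = white[i];
    double yg = hpbG[0] * xg + zg1;
    zg1 = hpbG[1] * xg - hpaG[1] * yg + zg2;
    zg2 = hpbG[2] * xg - hpaG[2] * yg;
    yg *= 1.0 - st[7] * (1.0 + std::sin(phTG)) / 2.0;

    const double mix = st[8] * delta + st[9] * theta + st[10] * alpha +
                       st[11] * yb + st[12] * yg;

    // 4-bit mid-tread crusher over [-1, 1] (round half to even, as R)
    double cr = std::nearbyint(mix * q16) / q16;
    if (cr > 1.0) cr = 1.0; else if (cr < -1.0) cr = -1.0;

    const double fade = st[14] * M_PI / 2.0;
    const double faded = std::cos(fade) * mix + std::sin(fade) * cr;

    // regional resonance: dry/wet blend with the constant-peak-gain
    // band-pass; the wet fraction (Q - 1)/10 makes low-entropy frames
    // resonant and selective while leaving high-entropy frames broadband
    const double q = st[13] > 1e-6 ? st[13] : 1e-6;
    const double alphaC = sw / (2.0 * q);
    const double a0 = 1.0 + alphaC;
    const double b0 = alphaC / a0;
    const double b2 = -alphaC / a0;
    const double a1 = -2.0 * cw / a0;
    const double a2 = (1.0 - alphaC) / a0;
    const double yr = b0 * faded + zr1;
    zr1 = -a1 * yr + zr2;
    zr2 = b2 * faded - a2 * yr;
    double w = (q - qBase) / qSpan;
    if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;
    y[i] = (1.0 - w) * faded + w * yr;
  }
  return y;
}
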