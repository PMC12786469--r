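---
title: "Parametric EEG sonification: methods and design notes"
author: "eegsonify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric EEG sonification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsonify)
```

# The problem

Alzheimer's disease leaves a well-documented signature in the resting
EEG: relative power rises in the slow delta (1--4 Hz) and theta
(4--8 Hz) bands, falls in alpha (8--13 Hz), beta (13--30 Hz) and gamma
(30--45 Hz), and the power spectrum flattens. These changes are
spectral, not morphological, which makes them a natural target for
*parameter-mapping sonification*: instead of playing the (infrasonic)
EEG waveform itself, per-window spectral features drive the parameters
of an audio synthesiser, so group differences become audible timbre
differences that an untrained listener can classify.

`eegsonify` implements that pipeline end to end — feature extraction,
offline synthesis, objective acoustic validation, and the statistics
for evaluating human listener panels — together with a seeded
synthetic-EEG generator so every stage is testable without clinical
recordings.

# Feature extraction

Analysis operates on 2 s sliding windows with a 1 s step (50% overlap).
Within each window the power spectral density is estimated by Welch's
method. The paperless internals of the estimator were fixed once:

* 1 s Hann-tapered segments at 50% overlap (three averaged segments per
  window), giving 1 Hz resolution — the coarsest grid that still
  resolves the 1 Hz lower delta edge while averaging enough segments to
  tame variance;
* segments are mean-removed before tapering;
* band edges are half-open `[lo, hi)` with the gamma upper edge closed
  at 45 Hz, so the five bands tile 1--45 Hz exactly and relative powers
  sum to 1 by construction.

Relative band power is band power divided by total 1--45 Hz power; no
further min--max rescaling is applied before the mapping (the simplest
reading of "normalized relative power" — the quantity is already in
[0, 1]). Normalized spectral entropy uses the natural-log Shannon
entropy of the 1--45 Hz bins divided by `log(K)`, so a single spectral
line scores 0 and a flat spectrum 1.

Channels are grouped into ten topographic regions (frontal, central,
parietal, occipital, temporal × left/right). Midline channels (Fz, Cz,
Pz) contribute half weight to each hemisphere. The regional quantity is
the *weighted mean PSD* of the member channels, from which regional
band powers and entropy are computed; averaging the spectra (rather
than the per-channel features) is the one choice that gives the
regional entropy a defensible meaning, since the entropy of a mean
spectrum is itself a spectral entropy while a mean of entropies is not.
The 19-channel montage carries no Oz, so the occipital regions hold
O1/O2 only; the montage table is an argument everywhere it is used.
Trailing partial windows are dropped and timestamps mark window starts,
keeping every window's statistics identical.

# The band-to-timbre mapping

Each region owns five sound sources, one per band, with per-window
parameters (P = relative power, H = normalized entropy):

| band  | source                       | mapped parameter                |
|-------|------------------------------|---------------------------------|
| delta | sine oscillator              | f = 45 + 50 P (45--95 Hz)       |
| theta | sine oscillator              | f = 90 + 80 P (90--170 Hz)      |
| alpha | triangle oscillator          | f = 180 + 160 P, detune ±(6+14H) cents |
| beta  | pink noise, 600 Hz high-pass | tremolo rate 3 + 14 P Hz        |
| gamma | white noise, 2 kHz high-pass | tremolo rate 5 + 20 P Hz        |

Dynamic controls: source gains g = P^0.85 (perceptual compression of
the dynamic range); tremolo depths 0.1 + 0.8 H (beta) and 0.15 + 0.8 H
(gamma); a clean/bit-crushed (4-bit) equal-power crossfade at position
0.15 + 0.85 H; and a regional band-pass at a fixed 1000 Hz center with
Q = 1 + 10(1 − H), so low-entropy (ordered) spectra sound resonant and
selective while high-entropy spectra sound broad and rough.

Choices the published constants do not pin down, fixed here once:

* **Tremolo law** — sinusoidal LFO with gain in `[1 − d, 1]`.
* **Crossfade law** — equal-power (cos/sin), the standard
  constant-loudness choice.
* **Detune schedule** — one uniform draw in ±(6 + 14 H) cents per
  window from a seeded substream.
* **Filters** — 2nd-order Butterworth high-passes for the noise
  sources. The regional "band-pass" is realized as a dry/wet resonance
  blend, `y = (1-w)·x + w·BPF_Q(x)` with a constant-peak-gain biquad
  and wet fraction `w = (Q-1)/10`: Q = 1 leaves the mix untouched and
  Q = 11 is the full narrowband. A literal insert band-pass at 1000 Hz
  would attenuate both the sub-100 Hz oscillators and the >2 kHz noise
  by well over 20 dB at every admissible Q, which is incompatible with
  the documented acoustic profile of the rendered sonifications
  (roughly 30% of energy below 100 Hz and 35% above 2 kHz); the blend
  preserves that broadband profile while still making low-entropy
  frames audibly more resonant and selective, which is the stated
  perceptual role of the Q modulation.
* **Inter-band levels** — sources carry fixed pre-mix levels
  (δ 0.5, θ 0.6, α 0.5, β 0.75, γ 1.0) beneath the mapped gains. The
  original mixing levels are undocumented, so these were calibrated
  once by nonnegative least squares of each source's solo rendered
  energy against the published control-group energy distribution
  across the six descriptor ranges, then rounded; they are constants,
  not fitted per run.
* **Bit-crusher** — uniform mid-tread quantizer over [−1, 1]
  (`round(x·8)/8` at 4 bits); mix samples beyond ±1 clip onto the grid.

# Rendering

Synthesis is offline at a fixed 48 kHz mono, one second of audio per
feature window. All parameter transitions use 80 ms exponential-approach
ramps (time constant 80 ms / ln 100, i.e. within 1% of the target at
80 ms), which keeps transitions click-free and testable. Oscillators
are phase-continuous accumulators. Region renders mix at −6 dB for the
focused region and −24 dB elsewhere (−6 dB everywhere for the
"all-regions" mix), and the master is peak-normalized to −1 dBFS *only
if it would clip*, since every descriptor used downstream is invariant
to positive rescaling.

The per-region chain is implemented twice: as composable, individually
tested R operators (`oscSine`, `oscTriangle`, `noisePink`,
`applyTremolo`, `bitcrush`, `crossfade`, `rampTrack`) and as a
single-pass compiled kernel used by `renderRegion` for cohort-scale
work; a unit test asserts the two agree to 1e-8 on a multi-window
render. The per-window detune is folded into a single effective alpha
frequency (f·2^(cents/1200)) before ramping. Pink noise uses the
Voss–McCartney multi-rate sum (16 rows), which gives the −3 dB/octave
slope to within the tested ±0.2 on the log–log fit; noise rows are
zero-mean uniform draws, whose 16-fold sum is near-Gaussian, and every
noise source draws from a counter-based seed substream keyed by
(subject, region, band) so edits to one subject never perturb another.

# Acoustic validation

Descriptors are computed from one STFT pass (Hann, frame 2048, hop 512
— conventional audio-analysis defaults at 48 kHz):

* spectral centroid: magnitude-weighted mean frequency per frame,
  averaged over non-silent frames;
* band energy fractions for 45--95, 90--170, 180--340, 600--2000 Hz,
  <100 Hz and >2000 Hz, from the pooled (frame-summed) power spectrum
  (the 45--95 and <100 Hz ranges overlap; both are reported as
  printed);
* temporal CV: SD/mean of the frame RMS envelope;
* normalized Shannon entropy of the pooled power spectrum;
* harmonicity: energy(<100 Hz) / energy(>2000 Hz), with the denominator
  floored at 1e−12 of total energy so pure low-frequency signals report
  a finite capped ratio.

Group comparison uses Welch's unequal-variance t-test per descriptor,
Benjamini–Hochberg FDR across the descriptor family (descriptors with
zero variance in both groups are flagged and excluded), and Cohen's d
with pooled SD.

# Listener statistics

Per evaluator: accuracy, sensitivity, specificity, PPV and NPV (zero
denominators reported as undefined, never 0; missing ratings excluded
from that evaluator's n, which is always taken from the supplied
matrix, never hard-coded). Each evaluator's correct count is tested
with an exact two-tailed binomial test — the minimum-likelihood tail
definition — against the probability-matching chance level
p² + (1 − p)², which is 50.58% for 36 vs 29 subjects; Holm's step-down
correction controls the family-wise error across evaluators.

Panel-level significance uses a label-permutation test: diagnostic
labels are shuffled across subjects with the rating matrix fixed, and
the statistic is the mean per-evaluator accuracy. The primary p-value
is the add-one estimator (1 + B)/(1 + N), which cannot be zero; the
naive proportion is also reported. The default is 10,000 permutations.

Inter-rater agreement is Fleiss' (1971) kappa on the subjects rated by
every evaluator (listwise exclusion, mirroring the differing Ns between
the metric and agreement analyses), with a nonparametric bootstrap CI
(resampling items, not raters; 1000 iterations; percentile 2.5/97.5).
If all raters are unanimous on a single category the expected agreement
is 1 and kappa is reported as undefined.

Statistical power is estimated by Monte Carlo: evaluator accuracies are
drawn from a normal distribution clipped to [0, 1], per-subject
correctness is Bernoulli, and each simulated panel is tested with the
permutation test at level alpha. This simulation model is deliberately
documented as a model choice — the distributional form of "the observed
effect" is the least constrained part of the published analysis, so the
package claims calibration at the null and high power at the observed
effect size, not any specific third-digit power value.

# The synthetic-EEG generator

The generator exists so the full pipeline can be exercised and
regression-tested without any clinical data. Each channel is a sum of
five band-limited noise components (white noise through a 4th-order
Butterworth band-pass per band), amplitude-scaled to hit the profile's
target relative powers. Because filter skirts and Welch leakage
redistribute a few percent of power between adjacent bands, the scaling
is solved exactly: each component's Welch-domain band-power split is
measured and the 5×5 linear system is solved for the mixing powers, so
extracted mean relative powers recover the target weights to within
~0.01 at 60 s (the tested bound is 0.03).

The default group profiles are *directional stand-ins*, chosen once:
AD-like (δ .30, θ .30, α .15, β .15, γ .10) and control-like (δ .20,
θ .15, α .30, β .22, γ .13). They encode the sign structure of the
published biomarkers — elevated delta/theta, reduced alpha/beta/gamma —
at separations a clinician would call a clear group effect, not any
fitted cohort magnitudes. Per-subject weights add uniform jitter
(±0.1 by default) before renormalizing, with a 0.01 floor; cohorts are
36 AD-like + 29 control-like by default, matching the study's group
sizes.

Spectral entropy is *not* forced: it emerges from the band weights, and
for flat-in-band noise the peakier AD-like profile measures *lower*
entropy (≈0.81) than control (≈0.87) — the reverse of the EEG
biomarker direction for entropy itself. This is accepted deliberately:
every group-difference direction the acoustic validation asserts
(including the lower temporal CV of AD-like sonifications, which the
source analysis itself notes is driven by oscillator dominance rather
than entropy) is reproduced under these emergent values, and forcing
entropy would conflict with the power constraints. Consequently the
entropy-driven contrasts (fade, tremolo depth, Q) are exercised in the
direction opposite to real AD EEG; what the synthetic cohort validates
is the sign-faithfulness of the *power-driven* acoustic pathway plus
the internal consistency of the entropy pathway, not a claim about real
patients.

What the generator does **not** emulate: 1/f background, artifacts
(blinks, EMG), nonstationarity, inter-channel correlation structure, or
realistic entropy elevation. Passing tests therefore show the pipeline
is correct and directionally faithful, not that real-cohort effect
magnitudes would be reproduced.

# Numerical and scale choices

* Window grids: with the default configuration the Welch segment grid
  aligns across sliding windows, so segment periodograms are computed
  once per channel and windows average contiguous runs of them; a
  non-aligned configuration falls back to per-window estimation.
* Degenerate inputs: zero-power windows are rejected in analysis;
  all-zero feature rows are allowed in synthetic inputs and render to
  digital silence; silent audio is rejected by every descriptor.
* The regression and acceptance tests run the full chain at study
  scale (36 + 29 subjects, 60 s recordings, 19 channels, 48 kHz
  renders) — chosen as the smallest cohort that pins down all eight
  group-difference signs with comfortable margins — and desk-scale
  property tests elsewhere (3--8 windows, single channels).
* Permutation and bootstrap defaults (10,000 / 1000) follow the
  published analysis; tests use smaller seeded counts where only
  calibration, not precision, is at stake.

# Worked example

```{r example, eval = FALSE}
cohort <- generateCohort(nAd = 3, nControl = 3, durationS = 20, seed = 1)
sf <- extractSubject(cohort[[1]], id = names(cohort)[1])
audio <- renderSubject(sf, focus = "all", seed = 1)
writeWav(audio, "sub-001.wav")
acousticDescriptors(audio)

truth <- cohortManifest(cohort)$group
rm <- generateRatingMatrix(truth, evaluatorAccuracies = rep(0.8, 8),
                           seed = 2)
evaluatePanel(rm)
permutationTestMeanAccuracy(rm, nPerm = 1000, seed = 3)
```

# Known limitations

* The synthesis is not bit-compatible with any browser implementation;
  it reproduces the documented processing logic, not a specific codec.
* Entropy of the synthetic profiles runs opposite to the clinical
  direction (see above).
* The temporal-CV group contrast does not reproduce on synthetic
  cohorts — and structurally cannot. In a rendered subject the RMS
  envelope varies mainly because the per-window band-power estimates
  jitter (three averaged Welch segments per window), and that jitter
  loads on whichever sources carry the most energy: the steady-state
  CV of an AD-like render is ~0.29 from the tonal sources alone versus
  ~0.04 under constant features. Real cohorts order the CV the other
  way through temporal band-power dynamics (stable high-amplitude slow
  rhythms in AD, relatively more variable fast activity in controls)
  that a stationary noise generator does not possess; the corresponding
  end-to-end check documents this as an expected failure rather than
  weakening the assertion.
* Regional features in real data differ across regions; the generator
  gives every channel the same profile, so regional contrasts are not
  exercised beyond symmetry checks.
* EDF support is deliberately minimal (16-bit, uniform rate, 1 s
  records) — enough for round-trip testing, not a general clinical
  reader; mismatched sampling rates are rejected rather than resampled.
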