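# Elementary synthesis operators: oscillators, noise sources, tremolo,
# bit-crusher, equal-power crossfade, exponential parameter ramps.

#' Phase-continuous sine oscillator
#'
#' @param freqTrack per-sample instantaneous frequency (Hz), all > 0.
#' @param fs sampling rate (Hz).
#' @return Unit-amplitude sample vector of the same length.
#' @export
oscSine <- function(freqTrack, fs) {
  if (!length(freqTrack)) return(numeric(0))
  if (any(freqTrack <= 0)) stop("frequencies must be positive")
  phase <- 2 * pi * (cumsum(freqTrack) - freqTrack[1]) / fs
  sin(phase)
}

#' Phase-continuous triangle oscillator with micro-detune
#'
#' The effective frequency is \code{freq * 2^(cents/1200)}; the waveform
#' is a unit-amplitude triangle whose fundamental sits at the effective
#' frequency.
#'
#' @param freqTrack per-sample base frequency (Hz).
#' @param detuneCentsTrack per-sample detune (cents; scalar recycled).
#' @param fs sampling rate (Hz).
#' @return Sample vector in [-1, 1].
#' @export
oscTriangle <- function(freqTrack, detuneCentsTrack = 0, fs) {
  if (!length(freqTrack)) return(numeric(0))
  f <- freqTrack * 2^(rep_len(detuneCentsTrack, length(freqTrack)) / 1200)
  if (any(f <= 0)) stop("frequencies must be positive")
  # cycle phase in [0, 1); triangle rises 0->1 over the first half cycle
  cyc <- ((cumsum(f) - f[1]) / fs) %% 1
  4 * abs(cyc - 0.5) - 1
}

#' Pink noise (1/f spectrum) via the Voss-McCartney multi-rate sum
#'
#' Sums \code{nRows} white-noise rows held for 1, 2, 4, ... samples,
#' giving an approximately -3 dB/octave power decay across the audio
#' band. Rows are zero-mean uniform draws (their 16-fold sum is
#' near-Gaussian); output is normalized to unit standard deviation.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz) (kept for interface symmetry).
#' @param seed integer seed.
#' @param nRows number of octave rows.
#' @return Sample vector of length \code{n}, unit SD, ~zero mean.
#' @export
noisePink <- function(n, fs = 48000, seed = 1, nRows = 16) {
  stopifnot(n >= 1)
  m <- sum(ceiling(n / 2^(seq_len(nRows) - 1)))
  x <- .vossExpand(withSeed(seed, runif(m, -1, 1)), n, nRows)
  x <- x - mean(x)
  x / sd(x)
}

#' White noise, zero mean, unit SD
#'
#' Spectrally flat uniform noise (the synthesis chain band-filters it,
#' so the marginal distribution is immaterial).
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return Sample vector of length \code{n}.
#' @export
noiseWhite <- function(n, seed = 1) {
  stopifnot(n >= 1)
  x <- withSeed(seed, runif(n, -1, 1))
  x <- x - mean(x)
  x / sd(x)
}

#' Sinusoidal tremolo (amplitude modulation)
#'
#' The gain oscillates in [1 - d, 1]:
#' \code{y = x * (1 - d * (1 + sin(phi)) / 2)} with \code{phi} the
#' accumulated modulator phase, so depth 0 is the identity and depth 1
#' swings the gain fully to zero.
#'
#' @param x input samples.
#' @param rateTrack per-sample modulation rate (Hz; scalar recycled).
#' @param depthTrack per-sample modulation depth in [0, 1] (recycled).
#' @param fs sampling rate (Hz).
#' @return Modulated samples.
#' @export
applyTremolo <- function(x, rateTrack, depthTrack, fs) {
  if (!length(x)) return(numeric(0))
  rate <- rep_len(rateTrack, length(x))
  depth <- rep_len(depthTrack, length(x))
  if (any(depth < 0 | depth > 1)) stop("tremolo depth must lie in [0, 1]")
  phase <- 2 * pi * (cumsum(rate) - rate[1]) / fs
  x * (1 - depth * (1 + sin(phase)) / 2)
}

#' Bit-crusher (uniform mid-tread quantizer)
#'
#' Quantizes to \code{2^bits} levels over [-1, 1]:
#' \code{y = round(x * 2^(bits-1)) / 2^(bits-1)}, clipped to [-1, 1].
#'
#' @param x input samples (nominally in [-1, 1]; values beyond clip).
#' @param bits bit depth (>= 1); default 4.
#' @return Quantized samples.
#' @examples
#' bitcrush(0.3, 4)  # 0.25
#' @export
bitcrush <- function(x, bits = 4) {
  if (bits < 1) stop("bits must be at least 1")
  q <- 2^(bits - 1)
  pmin(pmax(round(x * q) / q, -1), 1)
}

#' Equal-power crossfade between two signals
#'
#' \code{y = cos(fade * pi/2) * clean + sin(fade * pi/2) * crushed}, so
#' fade 0 passes the clean signal exactly, fade 1 the crushed one, and
#' the two coefficients keep constant summed power in between.
#'
#' @param clean,crushed equal-length sample vectors.
#' @param fadeTrack per-sample fade position in [0, 1] (scalar recycled).
#' @return Crossfaded samples.
#' @export
crossfade <- function(clean, crushed, fadeTrack) {
  if (length(clean) != length(crushed))
    stop("clean and crushed must have equal length")
  fade <- rep_len(fadeTrack, length(clean))
  if (any(fade < 0 | fade > 1)) stop("fade must lie in [0, 1]")
  cos(fade * pi / 2) * clean + sin(fade * pi / 2) * crushed
}

#' Exponential parameter ramp track
#'
#' Expands per-window parameter values into a per-sample automation
#' track. At each window boundary the track moves from its current value
#' toward the new target along an exponential-approach curve with time
#' constant \code{rampS / ln(100)}, so it is within 1\% of the target at
#' \code{rampS} seconds, monotone during each ramp, and continuous across
#' successive steps.
#'
#' @param values one parameter value per window.
#' @param stepS window step (s).
#' @param rampS ramp time (s); must be positive and less than
#'   \code{stepS}.
#' @param fs sampling rate (Hz).
#' @return Numeric vector of length \code{length(values) * stepS * fs}.
#' @export
rampTrack <- function(values, stepS, rampS, fs) {
  if (rampS <= 0) stop("rampS must be positive")
  if (rampS >= stepS) stop("rampS must be shorter than the window step")
  nStep <- round(stepS * fs)
  tau <- rampS / log(100)
  decay <- exp(-(seq_len(nStep)) / (fs * tau))
  out <- numeric(length(values) * nStep)
  cur <- values[1]
  for (j in seq_along(values)) {
    tgt <- values[j]
    block <- tgt + (cur - tgt) * decay
    out[((j - 1) * nStep + 1):(j * nStep)] <- block
    cur <- block[nStep]
  }
  out
}

# 2nd-order Butterworth high-pass (causal), used on beta/gamma noise
.highpass <- function(x, cutoff, fs) {
  bf <- signal::butter(2, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filter(bf, x))
}
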