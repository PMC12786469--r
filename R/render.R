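# Offline rendering: per-region synthesis chain and the 10-region
# subject mix.

#' Render one region's sonification
#'
#' Implements the regional synthesis chain: five band sources (sine delta
#' and theta, detuned triangle alpha, 600 Hz high-passed pink noise with
#' tremolo for beta, 2000 Hz high-passed white noise with tremolo for
#' gamma) scaled by the mapped gains and summed; the mix is split into a
#' clean and a 4-bit bit-crushed channel, recombined by the
#' entropy-driven equal-power crossfade, and shaped by the regional
#' band-pass filter (1000 Hz center, entropy-driven Q, ramped per
#' window). All per-window parameters move along 80 ms exponential ramps.
#' Fully deterministic given the seed.
#'
#' @param features a \code{WindowedFeatures} (one region).
#' @param consts a \code{\link{mappingConstants}} list.
#' @param fs audio sampling rate (Hz); default 48000.
#' @param seed integer seed (detune draws and noise substreams).
#' @return An \code{AudioBuffer} of duration \code{nWindows * stepS}.
#' @export
renderRegion <- function(features, consts = mappingConstants(),
                         fs = 48000, seed = 1) {
  stopifnot(is(features, "WindowedFeatures"))
  W <- length(features@timestamps)
  if (W < 1) stop("features must contain at least one window")
  stepS <- if (W > 1) median(diff(features@timestamps)) else 1
  P <- features@relPower
  H <- features@entropy
  params <- withSeed(substreamSeed(seed, 101), lapply(seq_len(W), function(i)
    mapFrame(P[i, ], H[i], consts)))
  n <- W * round(stepS * fs)

  # the per-window detune folds into one effective alpha frequency,
  # ramped as a single parameter
  lv <- consts$sourceLevels
  tgt <- t(vapply(params, function(p)
    c(p$fDelta, p$fTheta, p$fAlpha * 2^(p$detuneAlpha / 1200), 0,
      p$tremRateBeta,
      p$tremRateGamma, p$tremDepthBeta, p$tremDepthGamma,
      lv[["delta"]] * p$gains[["delta"]],
      lv[["theta"]] * p$gains[["theta"]],
      lv[["alpha"]] * p$gains[["alpha"]],
      lv[["beta"]] * p$gains[["beta"]],
      lv[["gamma"]] * p$gains[["gamma"]], p$qFactor, p$fade),
    numeric(15)))
  bfB <- signal::butter(2, consts$betaHpCut / (fs / 2), type = "high")
  bfG <- signal::butter(2, consts$gammaHpCut / (fs / 2), type = "high")
  out <- .renderRegionCore(
    tgt, stepS, consts$rampS, fs,
    noisePink(n, fs, seed = substreamSeed(seed, 102)),
    noiseWhite(n, seed = substreamSeed(seed, 103)),
    bfB$b, bfB$a, bfG$b, bfG$a,
    consts$regionBpCenter, consts$q[1], consts$q[2],
    as.integer(consts$bitDepth))
  audioBuffer(out, fs)
}

#' Render a subject's full sonification
#'
#' Renders the 10 regional synthesizers and mixes them with -6 dB on the
#' focused region and -24 dB on the others (\code{focus = "all"} applies
#' -6 dB everywhere). The master mix is peak-normalized to -1 dBFS
#' (0.891) only if it would clip, preserving relative dynamics otherwise.
#'
#' @param subject a \code{SubjectFeatures}.
#' @param focus a region code or \code{"all"}.
#' @param consts a \code{\link{mappingConstants}} list.
#' @param fs audio sampling rate (Hz).
#' @param seed integer seed; regions use substreams so single-region
#'   renders reproduce their contribution to the mix.
#' @return An \code{AudioBuffer}.
#' @export
renderSubject <- function(subject, focus = "all",
                          consts = mappingConstants(), fs = 48000,
                          seed = 1) {
  stopifnot(is(subject, "SubjectFeatures"))
  if (!(focus == "all" || focus %in% REGION_CODES))
    stop("unknown focus region: ", focus)
  gFocus <- 10^(consts$focusGainDb / 20)
  gOther <- 10^(consts$nonfocusGainDb / 20)
  acc <- NULL
  for (ri in seq_along(REGION_CODES)) {
    r <- REGION_CODES[ri]
    buf <- renderRegion(subject@regions[[r]], consts, fs,
                        seed = substreamSeed(seed, ri))
    g <- if (focus == "all" || focus == r) gFocus else gOther
    acc <- if (is.null(acc)) g * samples(buf) else acc + g * samples(buf)
  }
  peak <- max(abs(acc))
  if (peak > 1) acc <- acc * (0.891 / peak)
  audioBuffer(acc, fs)
}
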