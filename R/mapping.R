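# Band-to-timbre parameter mapping: per-window spectral features become
# oscillator frequencies, gains, tremolo rates/depths, filter Q and
# crossfade position.

#' Synthesis mapping constants
#'
#' All affine mapping ranges and fixed synthesis constants. Defaults are
#' the published mapping: delta pitch 45--95 Hz, theta 90--170 Hz, alpha
#' 180--340 Hz with +/-(6 + 14 H) cent micro-detune, beta tremolo
#' 3--17 Hz, gamma tremolo 5--25 Hz, gain law P^0.85, regional band-pass
#' Q = 1 + 10 (1 - H) at a fixed 1000 Hz center, clean/bit-crushed
#' crossfade 0.15 + 0.85 H with a 4-bit crusher, tremolo depths
#' 0.1 + 0.8 H (beta) and 0.15 + 0.8 H (gamma), beta/gamma source
#' high-pass cutoffs 600/2000 Hz, 80 ms exponential parameter ramps, and
#' regional gains of -6 dB (focused) / -24 dB (non-focused).
#'
#' @param deltaF,thetaF,alphaF c(base, span) Hz of the oscillator pitch maps.
#' @param alphaDetune c(base, span) cents of the detune magnitude map.
#' @param betaTrem,gammaTrem c(base, span) Hz of the tremolo rate maps.
#' @param gainExponent exponent of the perceptual gain compression.
#' @param q c(base, span) of the Q map (driven by 1 - H).
#' @param fade c(base, span) of the crossfade map.
#' @param dBeta,dGamma c(base, span) of the tremolo depth maps.
#' @param betaHpCut,gammaHpCut source high-pass cutoffs (Hz).
#' @param sourceLevels named per-band pre-mix amplitude levels applied on
#'   top of the mapped gains; calibrated so the rendered energy
#'   distribution of a typical subject matches the published validation
#'   profile (see the methods vignette).
#' @param regionBpCenter regional band-pass center frequency (Hz).
#' @param bitDepth bit-crusher depth in bits.
#' @param rampS parameter ramp time constant target (s).
#' @param focusGainDb,nonfocusGainDb regional gains (dB).
#' @return A list of class \code{MappingConstants}.
#' @export
mappingConstants <- function(deltaF = c(45, 50), thetaF = c(90, 80),
                             alphaF = c(180, 160), alphaDetune = c(6, 14),
                             betaTrem = c(3, 14), gammaTrem = c(5, 20),
                             gainExponent = 0.85, q = c(1, 10),
                             fade = c(0.15, 0.85), dBeta = c(0.1, 0.8),
                             dGamma = c(0.15, 0.8), betaHpCut = 600,
                             gammaHpCut = 2000,
                             sourceLevels = c(delta = 0.5, theta = 0.6,
                                              alpha = 0.5, beta = 0.75,
                                              gamma = 1),
                             regionBpCenter = 1000,
                             bitDepth = 4, rampS = 0.08,
                             focusGainDb = -6, nonfocusGainDb = -24) {
  consts <- list(deltaF = deltaF, thetaF = thetaF, alphaF = alphaF,
                 alphaDetune = alphaDetune, betaTrem = betaTrem,
                 gammaTrem = gammaTrem, gainExponent = gainExponent,
                 q = q, fade = fade, dBeta = dBeta, dGamma = dGamma,
                 betaHpCut = betaHpCut, gammaHpCut = gammaHpCut,
                 sourceLevels = sourceLevels,
                 regionBpCenter = regionBpCenter, bitDepth = bitDepth,
                 rampS = rampS, focusGainDb = focusGainDb,
                 nonfocusGainDb = nonfocusGainDb)
  spans <- vapply(consts[c("deltaF", "thetaF", "alphaF", "alphaDetune",
                           "betaTrem", "gammaTrem", "q", "fade",
                           "dBeta", "dGamma")], `[`, numeric(1), 2)
  if (any(spans <= 0)) stop("all mapping spans must be positive")
  if (bitDepth < 1) stop("bitDepth must be at least 1")
  structure(consts, class = "MappingConstants")
}

#' Map one window's features to synthesis parameters
#'
#' Applies the affine mapping equations: pitch f_delta = 45 + 50 P_delta,
#' f_theta = 90 + 80 P_theta, f_alpha = 180 + 160 P_alpha; tremolo rates
#' 3 + 14 P_beta and 5 + 20 P_gamma; gains g_b = P_b^0.85; filter
#' Q = 1 + 10 (1 - H); crossfade 0.15 + 0.85 H; tremolo depths
#' 0.1 + 0.8 H and 0.15 + 0.8 H. The alpha detune is drawn uniformly in
#' +/-(6 + 14 H) cents from the current RNG state unless given.
#'
#' @param P named numeric of 5 relative band powers, each in [0, 1].
#' @param H normalized spectral entropy in [0, 1].
#' @param consts a \code{\link{mappingConstants}} list.
#' @param detune optional fixed detune (cents); if NULL, drawn randomly.
#' @return A named list of per-window synthesis parameters
#'   (\code{fDelta}, \code{fTheta}, \code{fAlpha}, \code{detuneAlpha},
#'   \code{tremRateBeta}, \code{tremRateGamma}, \code{tremDepthBeta},
#'   \code{tremDepthGamma}, \code{gains}, \code{qFactor}, \code{fade}).
#' @examples
#' mapFrame(c(delta = 1, theta = 0, alpha = 0, beta = 0, gamma = 0), 0)
#' @export
mapFrame <- function(P, H, consts = mappingConstants(), detune = NULL) {
  if (any(P < 0 | P > 1) || H < 0 || H > 1)
    stop("band powers and entropy must lie in [0, 1]")
  P <- P[BAND_NAMES]
  detuneMag <- consts$alphaDetune[1] + consts$alphaDetune[2] * H
  if (is.null(detune)) detune <- runif(1, -detuneMag, detuneMag)
  list(
    fDelta = consts$deltaF[1] + consts$deltaF[2] * P[["delta"]],
    fTheta = consts$thetaF[1] + consts$thetaF[2] * P[["theta"]],
    fAlpha = consts$alphaF[1] + consts$alphaF[2] * P[["alpha"]],
    detuneAlpha = detune,
    tremRateBeta = consts$betaTrem[1] + consts$betaTrem[2] * P[["beta"]],
    tremRateGamma = consts$gammaTrem[1] + consts$gammaTrem[2] * P[["gamma"]],
    tremDepthBeta = consts$dBeta[1] + consts$dBeta[2] * H,
    tremDepthGamma = consts$dGamma[1] + consts$dGamma[2] * H,
    gains = setNames(unname(P)^consts$gainExponent, BAND_NAMES),
    qFactor = consts$q[1] + consts$q[2] * (1 - H),
    fade = consts$fade[1] + consts$fade[2] * H)
}
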