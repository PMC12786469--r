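# Objective acoustic descriptors of rendered sonifications and the
# two-group comparison (Welch t, Benjamini-Hochberg FDR, Cohen's d).

# One STFT pass (Hann frame 2048, hop 512) computing everything the
# descriptors need: pooled power spectrum, frame-averaged centroid, and
# the frame RMS envelope. The loop lives in compiled code.
.stftStats <- function(x, fs, frame = 2048, hop = 512) {
  .stftStatsCore(as.numeric(x), fs, as.integer(frame), as.integer(hop))
}

.assertAudible <- function(audio) {
  stopifnot(is(audio, "AudioBuffer"))
  if (!length(samples(audio)) || all(samples(audio) == 0))
    stop("silent audio: descriptor undefined")
}

#' Spectral centroid
#'
#' Magnitude-weighted mean frequency per short-time frame (Hann 2048 /
#' hop 512), averaged over non-silent frames; the acoustic correlate of
#' perceived brightness.
#'
#' @param audio an \code{AudioBuffer}.
#' @return Centroid in Hz.
#' @export
spectralCentroid <- function(audio) {
  .assertAudible(audio)
  .stftStats(samples(audio), sampleRate(audio))$centroid
}

#' Default descriptor frequency ranges
#'
#' The printed validation ranges: 45--95, 90--170, 180--340 and
#' 600--2000 Hz (the mapped delta/theta/alpha/beta bands), plus the open
#' ranges below 100 Hz and above 2000 Hz. The 45--95 and <100 Hz ranges
#' overlap by construction; both are reported.
#'
#' @return Named list of length-2 numeric ranges (Hz); \code{Inf} marks
#'   an open upper end.
#' @export
descriptorRanges <- function() {
  list("e_45_95"    = c(45, 95),
       "e_90_170"   = c(90, 170),
       "e_180_340"  = c(180, 340),
       "e_600_2000" = c(600, 2000),
       "e_lt_100"   = c(-Inf, 100),
       "e_gt_2000"  = c(2000, Inf))
}

.rangeMask <- function(freqs, range) {
  if (!is.finite(range[1])) freqs < range[2]
  else if (!is.finite(range[2])) freqs > range[1]
  else freqs >= range[1] & freqs <= range[2]
}

#' Band energy fractions
#'
#' Fraction of total energy of the pooled (frame-averaged) power
#' spectrum inside each named frequency range.
#'
#' @param audio an \code{AudioBuffer}.
#' @param ranges named list of length-2 ranges in Hz (default
#'   \code{\link{descriptorRanges}}).
#' @return Named numeric vector of fractions in [0, 1].
#' @export
bandEnergyFractions <- function(audio, ranges = descriptorRanges()) {
  .assertAudible(audio)
  st <- .stftStats(samples(audio), sampleRate(audio))
  tot <- sum(st$poolPower)
  vapply(ranges, function(rg)
    sum(st$poolPower[.rangeMask(st$freqs, rg)]) / tot, numeric(1))
}

#' Temporal coefficient of variation of the RMS envelope
#'
#' SD divided by mean of the frame-wise RMS amplitude envelope (frame
#' 2048, hop 512); quantifies temporal loudness stability and is
#' invariant to rescaling the waveform.
#'
#' @param audio an \code{AudioBuffer}.
#' @return A non-negative scalar.
#' @export
temporalCV <- function(audio) {
  .assertAudible(audio)
  env <- .stftStats(samples(audio), sampleRate(audio))$rmsEnv
  if (length(env) < 10) stop("need at least 10 envelope frames")
  m <- mean(env)
  if (m <= 0) stop("zero-mean envelope: CV undefined")
  sd(env) / m
}

#' Shannon entropy of the audio power spectrum
#'
#' Normalized entropy (natural log over log bin count) of the pooled
#' power spectrum; 0 for a pure tone, approaching 1 for white noise.
#'
#' @param audio an \code{AudioBuffer}.
#' @return A value in [0, 1].
#' @export
audioSpectralEntropy <- function(audio) {
  .assertAudible(audio)
  st <- .stftStats(samples(audio), sampleRate(audio))
  keep <- st$freqs > 0
  p <- st$poolPower[keep] / sum(st$poolPower[keep])
  plogp <- ifelse(p > 0, p * log(p), 0)
  -sum(plogp) / log(sum(keep))
}

#' Harmonicity estimate
#'
#' Ratio of low-frequency (< 100 Hz) to high-frequency (> 2000 Hz)
#' energy, a proxy for harmonic-distortion balance. The denominator is
#' floored at 1e-12 of the total energy, so pure low-frequency signals
#' report the capped ceiling rather than dividing by zero.
#'
#' @param audio an \code{AudioBuffer}.
#' @return A non-negative ratio.
#' @export
harmonicityEstimate <- function(audio) {
  .assertAudible(audio)
  st <- .stftStats(samples(audio), sampleRate(audio))
  lo <- sum(st$poolPower[st$freqs < 100])
  hi <- sum(st$poolPower[st$freqs > 2000])
  lo / max(hi, 1e-12 * sum(st$poolPower))
}

#' All acoustic descriptors of one sonification
#'
#' Computes the full descriptor vector in one analysis pass: spectral
#' centroid, the six band energy fractions, temporal CV, normalized
#' spectral entropy, and the harmonicity estimate. All descriptors are
#' invariant to multiplying the waveform by a positive constant.
#'
#' @param audio an \code{AudioBuffer}.
#' @return Named numeric vector.
#' @export
acousticDescriptors <- function(audio) {
  .assertAudible(audio)
  st <- .stftStats(samples(audio), sampleRate(audio))
  tot <- sum(st$poolPower)
  fr <- vapply(descriptorRanges(), function(rg)
    sum(st$poolPower[.rangeMask(st$freqs, rg)]) / tot, numeric(1))
  keep <- st$freqs > 0
  p <- st$poolPower[keep] / sum(st$poolPower[keep])
  plogp <- ifelse(p > 0, p * log(p), 0)
  lo <- sum(st$poolPower[st$freqs < 100])
  hi <- sum(st$poolPower[st$freqs > 2000])
  m <- mean(st$rmsEnv)
  c(spectral_centroid = st$centroid, fr,
    temporal_cv = if (m > 0) sd(st$rmsEnv) / m else NA_real_,
    spectral_entropy = -sum(plogp) / log(sum(keep)),
    harmonicity = lo / max(hi, 1e-12 * tot))
}

#' Compare acoustic descriptors between two groups
#'
#' Per descriptor: Welch (unequal-variance) two-sample t-test,
#' Benjamini-Hochberg FDR correction across the descriptor family, and
#' Cohen's d with pooled SD. Descriptors with zero variance in both
#' groups are flagged and excluded from the FDR family.
#'
#' @param descriptorsA,descriptorsB matrices or data.frames (rows =
#'   subjects, columns = descriptors) with matching column names.
#' @return A data.frame with one row per descriptor: group means and
#'   SDs, difference, t statistic, raw and FDR-adjusted p, Cohen's d.
#' @export
compareGroups <- function(descriptorsA, descriptorsB) {
  a <- as.matrix(descriptorsA); b <- as.matrix(descriptorsB)
  if (!identical(colnames(a), colnames(b)))
    stop("descriptor columns must match between groups")
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need at least 2 subjects per group")
  rows <- lapply(colnames(a), function(d) {
    xa <- a[, d]; xb <- b[, d]
    dm <- mean(xa) - mean(xb)
    degenerate <- sd(xa) == 0 && sd(xb) == 0
    if (degenerate) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
      dd <- if (dm == 0) 0 else NA_real_
    } else {
      tt <- t.test(xa, xb)
      sp <- sqrt(((length(xa) - 1) * sd(xa)^2 +
                  (length(xb) - 1) * sd(xb)^2) /
                   (length(xa) + length(xb) - 2))
      dd <- if (sp > 0) dm / sp else NA_real_
    }
    data.frame(descriptor = d,
               mean_a = mean(xa), sd_a = sd(xa),
               mean_b = mean(xb), sd_b = sd(xb),
               difference = dm,
               t = unname(tt$statistic), p = tt$p.value,
               cohens_d = dd)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}
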