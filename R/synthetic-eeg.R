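# Seeded synthetic EEG: band-weighted filtered-noise recordings and
# simulated evaluator rating matrices.

#' Default group spectral profiles
#'
#' Directional stand-ins for the spectral composition of the two groups:
#' the AD-like profile has elevated delta/theta and reduced
#' alpha/beta/gamma relative power; the control-like profile the reverse.
#' The \code{entropyLevel} slot records the approximate normalized
#' spectral entropy that emerges from these weights under the flat-in-band
#' noise model (it is not enforced).
#'
#' @return A \code{SpectralProfile}.
#' @export
adProfile <- function() {
  spectralProfile(c(delta = 0.30, theta = 0.30, alpha = 0.15,
                    beta = 0.15, gamma = 0.10),
                  entropyLevel = 0.85, label = "AD")
}

#' @rdname adProfile
#' @export
controlProfile <- function() {
  spectralProfile(c(delta = 0.20, theta = 0.15, alpha = 0.30,
                    beta = 0.22, gamma = 0.13),
                  entropyLevel = 0.91, label = "control")
}

# unit-variance band-limited noise: white noise through a 4th-order
# Butterworth band-pass (two cascaded biquads via filtfilt)
.bandNoise <- function(n, fs, lo, hi) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, rnorm(n + 2 * fs))  # pad to absorb edge ringing
  y <- y[(fs + 1):(fs + n)]
  y / sd(y)
}

#' Generate a synthetic multichannel EEG recording
#'
#' Each channel is an independent sum of band-limited noise components
#' (one per canonical band) amplitude-scaled so that the relative power
#' ratios over 1--45 Hz match the profile's band weights. Channels use
#' counter-based seed substreams, so the same (seed, channel) pair always
#' reproduces the same samples.
#'
#' @param profile a \code{SpectralProfile}.
#' @param durationS duration in seconds (>= 4).
#' @param fs sampling rate in Hz (>= 200; default 500).
#' @param seed integer seed.
#' @param channels channel names (default the 19-channel 10-20 set).
#' @param rmsUv overall RMS amplitude in microvolts.
#' @return An \code{EEGRecording}.
#' @examples
#' rec <- generateRecording(controlProfile(), durationS = 8, seed = 1)
#' @export
generateRecording <- function(profile, durationS, fs = 500, seed = 1,
                              channels = tenTwentyChannels(), rmsUv = 20) {
  stopifnot(is(profile, "SpectralProfile"))
  if (durationS < 4) stop("durationS must be at least 4 seconds")
  if (fs < 200) stop("fs must be at least 200 Hz")
  validObject(profile)
  n <- round(durationS * fs)
  bands <- eegBands()
  w <- unname(bandWeights(profile)[bands$name])
  nseg <- round(fs)
  sm <- matrix(0, nrow = length(channels), ncol = n,
               dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    comps <- lapply(seq_len(nrow(bands)), function(bi)
      withSeed(substreamSeed(seed, ci, bi),
               .bandNoise(n, fs, bands$fLo[bi], bands$fHi[bi])))
    # amplitude calibration: measure each component's Welch-domain band
    # power split and solve for the mixing powers that make the mixture's
    # relative band powers hit the profile weights
    B <- vapply(comps, function(u) {
      pg <- .segmentPeriodograms(u, fs, nseg, nseg %/% 2)
      psd <- rowMeans(pg$psd)
      vapply(seq_len(nrow(bands)), function(b)
        sum(psd[.bandMask(pg$freqs, bands$fLo[b], bands$fHi[b],
                          hiInclusive = b == nrow(bands))]),
        numeric(1))
    }, numeric(nrow(bands)))
    s <- tryCatch(solve(B, w), error = function(e) w / diag(B))
    s <- pmax(s, 1e-9 * max(s))
    x <- 0
    for (bi in seq_len(nrow(bands))) x <- x + sqrt(s[bi]) * comps[[bi]]
    sm[ci, ] <- x / sd(x) * rmsUv
  }
  new("EEGRecording", samples = sm, fs = fs, channelNames = channels,
      profile = profile, seed = as.integer(seed))
}

# perturb group weights additively, floor and renormalize
.jitterWeights <- function(w, jitter, seed) {
  if (jitter == 0) return(w)
  wj <- w + withSeed(seed, runif(length(w), -jitter, jitter))
  if (any(wj < 0.01)) {
    warning("jittered band weight clipped at the 0.01 floor")
    wj <- pmax(wj, 0.01)
  }
  wj / sum(wj)
}

#' Generate a synthetic two-group EEG cohort
#'
#' Per-subject band weights are the group profile perturbed by seeded
#' additive uniform jitter and renormalized to sum 1; weights that would
#' fall below 0.01 are clipped with a warning. Subject order (all AD-like
#' subjects first) and all seeds are deterministic functions of the master
#' seed, via counter-based substreams.
#'
#' @param nAd,nControl number of subjects per group (>= 1).
#' @param durationS per-subject duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed master integer seed.
#' @param jitter additive weight perturbation half-width, in [0, 0.5).
#' @param profiles named list with elements \code{AD} and \code{control},
#'   the group \code{SpectralProfile}s.
#' @return A named list of \code{EEGRecording}s (names sub-001, ...).
#' @export
generateCohort <- function(nAd, nControl, durationS = 60, fs = 500,
                           seed = 1, jitter = 0.1,
                           profiles = list(AD = adProfile(),
                                           control = controlProfile())) {
  stopifnot(nAd >= 1, nControl >= 1, jitter >= 0, jitter < 0.5)
  groups <- c(rep("AD", nAd), rep("control", nControl))
  out <- vector("list", length(groups))
  names(out) <- sprintf("sub-%03d", seq_along(groups))
  for (i in seq_along(groups)) {
    base <- profiles[[groups[i]]]
    w <- .jitterWeights(bandWeights(base), jitter,
                        substreamSeed(seed, i, 9999))
    prof <- spectralProfile(w, base@entropyLevel, groups[i])
    out[[i]] <- generateRecording(prof, durationS, fs,
                                  seed = substreamSeed(seed, i))
  }
  out
}

#' Cohort manifest table
#'
#' @param cohort list of \code{EEGRecording}s from
#'   \code{\link{generateCohort}}.
#' @return data.frame with subject id, group, seed and band weights.
#' @export
cohortManifest <- function(cohort) {
  do.call(rbind, lapply(names(cohort), function(id) {
    r <- cohort[[id]]
    w <- bandWeights(r@profile)
    cbind(data.frame(subject_id = id, group = groupLabel(r@profile),
                     seed = r@seed),
          as.data.frame(as.list(w)))
  }))
}

#' Simulate an evaluator rating matrix
#'
#' Each evaluator labels each subject correctly with probability equal to
#' that evaluator's accuracy, independently across cells; reproducible
#' from the seed.
#'
#' @param truth character vector of true groups ("AD"/"control").
#' @param evaluatorAccuracies numeric vector of per-evaluator accuracies
#'   in [0, 1].
#' @param seed integer seed.
#' @return A \code{RatingMatrix}.
#' @export
generateRatingMatrix <- function(truth, evaluatorAccuracies, seed = 1) {
  if (length(truth) == 0) stop("truth must be non-empty")
  if (any(evaluatorAccuracies < 0 | evaluatorAccuracies > 1))
    stop("accuracies must lie in [0, 1]")
  other <- ifelse(truth == "AD", "control", "AD")
  n <- length(truth)
  rat <- vapply(seq_along(evaluatorAccuracies), function(j) {
    ok <- withSeed(substreamSeed(seed, j),
                   rbinom(n, 1, evaluatorAccuracies[j]) == 1)
    ifelse(ok, truth, other)
  }, character(n))
  ratingMatrix(truth, matrix(rat, nrow = n))
}
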