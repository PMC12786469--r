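# S4 classes for the pipeline's central data objects.

BAND_NAMES <- c("delta", "theta", "alpha", "beta", "gamma")

REGION_CODES <- c("F-L", "F-R", "C-L", "C-R", "P-L", "P-R",
                  "O-L", "O-R", "T-L", "T-R")

GROUP_LEVELS <- c("AD", "control")

#' Canonical EEG frequency bands
#'
#' The five classical bands: delta [1, 4), theta [4, 8), alpha [8, 13),
#' beta [13, 30) and gamma [30, 45] Hz. Band edges are half-open so no
#' spectral bin is counted twice; the gamma upper edge is closed.
#'
#' @return A data.frame with columns \code{name}, \code{fLo}, \code{fHi}.
#' @export
eegBands <- function() {
  data.frame(name = BAND_NAMES,
             fLo  = c(1, 4, 8, 13, 30),
             fHi  = c(4, 8, 13, 30, 45),
             stringsAsFactors = FALSE)
}

#' Topographic region codes
#'
#' The ten scalp regions used for aggregation: frontal, central, parietal,
#' occipital and temporal, each split into left/right hemispheres.
#'
#' @return Character vector of the 10 region codes.
#' @export
regionCodes <- function() REGION_CODES

#' The 19-channel 10-20 montage channel set
#'
#' @return Character vector of the 19 scalp channel names.
#' @export
tenTwentyChannels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz",
    "C3", "C4", "Cz", "P3", "P4", "Pz",
    "O1", "O2", "T3", "T4", "T5", "T6")
}

#' SpectralProfile: target spectral composition of a synthetic recording
#'
#' @slot bandWeights named numeric, target relative power per band
#'   (delta/theta/alpha/beta/gamma), summing to 1.
#' @slot entropyLevel nominal normalized spectral entropy in [0, 1]. The
#'   generator does not force entropy; this records the approximate value
#'   that emerges from the band weights (see the methods vignette).
#' @slot label group tag, \code{"AD"} or \code{"control"}.
#' @export
setClass("SpectralProfile",
  representation(bandWeights = "numeric",
                 entropyLevel = "numeric",
                 label = "character"))

setValidity("SpectralProfile", function(object) {
  w <- object@bandWeights
  if (!identical(sort(names(w)), sort(BAND_NAMES)))
    return("bandWeights must be named exactly delta/theta/alpha/beta/gamma")
  if (any(w < 0) || any(w > 1)) return("band weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9) return("band weights must sum to 1")
  if (length(object@entropyLevel) != 1 ||
      object@entropyLevel < 0 || object@entropyLevel > 1)
    return("entropyLevel must be a single value in [0, 1]")
  if (!object@label %in% GROUP_LEVELS)
    return("label must be 'AD' or 'control'")
  TRUE
})

#' Construct a SpectralProfile
#'
#' @param bandWeights named numeric of 5 relative band powers summing to 1.
#' @param entropyLevel nominal normalized spectral entropy in [0, 1].
#' @param label group tag, \code{"AD"} or \code{"control"}.
#' @return A \code{SpectralProfile} object.
#' @examples
#' spectralProfile(c(delta = .2, theta = .2, alpha = .2, beta = .2,
#'                   gamma = .2), 1, "control")
#' @export
spectralProfile <- function(bandWeights, entropyLevel, label) {
  new("SpectralProfile", bandWeights = bandWeights[BAND_NAMES],
      entropyLevel = entropyLevel, label = label)
}

#' EEGRecording: a multichannel EEG recording
#'
#' @slot samples channels x time numeric matrix (microvolts); rownames are
#'   channel names.
#' @slot fs sampling rate in Hz.
#' @slot channelNames 10-20 channel labels.
#' @slot profile the generating \code{SpectralProfile} for synthetic
#'   recordings, or \code{NULL} for recordings read from disk.
#' @slot seed integer seed used to generate the recording (NA if not
#'   synthetic).
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", fs = "numeric",
                 channelNames = "character", profile = "ANY",
                 seed = "integer"))

setValidity("EEGRecording", function(object) {
  if (nrow(object@samples) != length(object@channelNames))
    return("one channel name per sample row required")
  if (length(object@fs) != 1 || object@fs <= 0)
    return("fs must be a single positive number")
  if (anyDuplicated(object@channelNames))
    return("duplicated channel names")
  TRUE
})

#' PowerSpectrum: a one-sided power spectral density estimate
#'
#' @slot freqs strictly increasing frequency grid (Hz).
#' @slot psd non-negative power density values (uV^2/Hz).
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", psd = "numeric"))

setValidity("PowerSpectrum", function(object) {
  if (length(object@freqs) != length(object@psd))
    return("freqs and psd must have equal length")
  if (is.unsorted(object@freqs, strictly = TRUE))
    return("freqs must be strictly increasing")
  if (any(object@psd < -1e-12)) return("psd must be non-negative")
  TRUE
})

#' WindowedFeatures: per-window spectral features of one channel or region
#'
#' @slot timestamps window start times in seconds.
#' @slot relPower windows x 5 matrix of relative band powers; each row
#'   sums to 1; columns named delta/theta/alpha/beta/gamma.
#' @slot entropy normalized spectral entropy per window, in [0, 1].
#' @export
setClass("WindowedFeatures",
  representation(timestamps = "numeric", relPower = "matrix",
                 entropy = "numeric"))

setValidity("WindowedFeatures", function(object) {
  n <- length(object@timestamps)
  if (nrow(object@relPower) != n || length(object@entropy) != n)
    return("timestamps, relPower rows and entropy must share length")
  if (!identical(colnames(object@relPower), BAND_NAMES))
    return("relPower columns must be delta/theta/alpha/beta/gamma")
  if (n > 0) {
    rs <- rowSums(object@relPower)
    # all-zero rows mark degenerate (silent) windows in synthetic inputs
    if (max(pmin(abs(rs - 1), rs)) > 1e-9)
      return("relative band powers must sum to 1 (or 0) per window")
    if (any(object@relPower < -1e-12) || any(object@relPower > 1 + 1e-12))
      return("relative band powers must lie in [0, 1]")
    if (any(object@entropy < -1e-12) || any(object@entropy > 1 + 1e-9))
      return("entropy must lie in [0, 1]")
  }
  TRUE
})

#' SubjectFeatures: regional spectral feature time series of one subject
#'
#' In-memory twin of the per-subject feature file (see
#' \code{\link{writeFeatures}}).
#'
#' @slot subjectId opaque subject identifier.
#' @slot fs original EEG sampling rate (Hz).
#' @slot windowS analysis window length (s).
#' @slot stepS window step (s).
#' @slot regions named list of \code{WindowedFeatures}, one per region
#'   code; all share timestamps.
#' @export
setClass("SubjectFeatures",
  representation(subjectId = "character", fs = "numeric",
                 windowS = "numeric", stepS = "numeric",
                 regions = "list"))

setValidity("SubjectFeatures", function(object) {
  if (!identical(sort(names(object@regions)), sort(REGION_CODES)))
    return("regions must be named by exactly the 10 region codes")
  ts0 <- object@regions[[1]]@timestamps
  for (r in object@regions) {
    if (!is(r, "WindowedFeatures")) return("regions must hold WindowedFeatures")
    if (!isTRUE(all.equal(r@timestamps, ts0)))
      return("all regions must share timestamps")
  }
  TRUE
})

#' AudioBuffer: a rendered mono sonification
#'
#' @slot samples mono float samples in [-1, 1].
#' @slot fs audio sampling rate (Hz), 48000 by default.
#' @export
setClass("AudioBuffer",
  representation(samples = "numeric", fs = "numeric"))

setValidity("AudioBuffer", function(object) {
  if (length(object@fs) != 1 || object@fs <= 0)
    return("fs must be a single positive number")
  TRUE
})

#' Construct an AudioBuffer
#' @param samples numeric vector of mono samples.
#' @param fs sampling rate in Hz (default 48000).
#' @return An \code{AudioBuffer}.
#' @export
audioBuffer <- function(samples, fs = 48000) {
  new("AudioBuffer", samples = as.numeric(samples), fs = fs)
}

#' RatingMatrix: listener classifications with ground truth
#'
#' @slot subjects subject identifiers.
#' @slot truth per-subject true group, \code{"AD"} or \code{"control"}.
#' @slot ratings subjects x evaluators character matrix of labels
#'   (\code{"AD"}/\code{"control"}; \code{NA} = missing).
#' @export
setClass("RatingMatrix",
  representation(subjects = "character", truth = "character",
                 ratings = "matrix"))

setValidity("RatingMatrix", function(object) {
  n <- length(object@subjects)
  if (length(object@truth) != n || nrow(object@ratings) != n)
    return("truth and ratings rows must match subjects")
  if (ncol(object@ratings) < 1) return("at least one evaluator required")
  if (!all(object@truth %in% GROUP_LEVELS))
    return("truth labels must be 'AD' or 'control'")
  vals <- object@ratings[!is.na(object@ratings)]
  if (!all(vals %in% GROUP_LEVELS))
    return("ratings must be 'AD', 'control' or NA")
  TRUE
})

#' Construct a RatingMatrix
#' @param truth character vector of true groups ("AD"/"control").
#' @param ratings subjects x evaluators character matrix (NA = missing).
#' @param subjects optional subject ids (default sub-001, ...).
#' @return A \code{RatingMatrix}.
#' @export
ratingMatrix <- function(truth, ratings, subjects = NULL) {
  ratings <- as.matrix(ratings)
  if (is.null(subjects)) subjects <- sprintf("sub-%03d", seq_along(truth))
  if (is.null(colnames(ratings)))
    colnames(ratings) <- sprintf("evaluator_%d", seq_len(ncol(ratings)))
  new("RatingMatrix", subjects = as.character(subjects),
      truth = as.character(truth), ratings = ratings)
}
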