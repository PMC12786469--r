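# Accessor generics and show methods.

#' Extract sample data
#' @param x an object with sample data.
#' @return For \code{EEGRecording}, the channels x time matrix; for
#'   \code{AudioBuffer}, the mono sample vector.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname samples
#' @export
setMethod("samples", "EEGRecording", function(x) x@samples)

#' @rdname samples
#' @export
setMethod("samples", "AudioBuffer", function(x) x@samples)

#' Sampling rate accessor
#' @param x an \code{EEGRecording} or \code{AudioBuffer}.
#' @return The sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "EEGRecording", function(x) x@fs)

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "AudioBuffer", function(x) x@fs)

#' Channel names accessor
#' @param x an \code{EEGRecording}.
#' @return Character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

#' Band weights accessor
#' @param x a \code{SpectralProfile}.
#' @return Named numeric vector of target relative band powers.
#' @export
setGeneric("bandWeights", function(x) standardGeneric("bandWeights"))

#' @rdname bandWeights
#' @export
setMethod("bandWeights", "SpectralProfile", function(x) x@bandWeights)

#' Group label accessor
#' @param x a \code{SpectralProfile} or \code{RatingMatrix}.
#' @return The group tag(s).
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname groupLabel
#' @export
setMethod("groupLabel", "SpectralProfile", function(x) x@label)

#' Regional features accessor
#' @param x a \code{SubjectFeatures}.
#' @param region optional region code; if omitted, the full named list.
#' @return A \code{WindowedFeatures} or list thereof.
#' @export
setGeneric("regionFeatures",
           function(x, region) standardGeneric("regionFeatures"))

#' @rdname regionFeatures
#' @export
setMethod("regionFeatures", "SubjectFeatures", function(x, region) {
  if (missing(region)) return(x@regions)
  if (!region %in% names(x@regions))
    stop("unknown region code: ", region)
  x@regions[[region]]
})

#' Subject id accessor
#' @param x a \code{SubjectFeatures}.
#' @return The subject identifier string.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname subjectId
#' @export
setMethod("subjectId", "SubjectFeatures", function(x) x@subjectId)

#' Relative band power accessor
#' @param x a \code{WindowedFeatures}.
#' @return Windows x 5 matrix of relative band powers.
#' @export
setGeneric("relPower", function(x) standardGeneric("relPower"))

#' @rdname relPower
#' @export
setMethod("relPower", "WindowedFeatures", function(x) x@relPower)

#' Spectral entropy accessor
#' @param x a \code{WindowedFeatures}.
#' @return Numeric vector of per-window normalized spectral entropy.
#' @export
setGeneric("entropyValues", function(x) standardGeneric("entropyValues"))

#' @rdname entropyValues
#' @export
setMethod("entropyValues", "WindowedFeatures", function(x) x@entropy)

#' Ratings accessor
#' @param x a \code{RatingMatrix}.
#' @return The subjects x evaluators character matrix.
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))

#' @rdname ratings
#' @export
setMethod("ratings", "RatingMatrix", function(x) x@ratings)

#' Ground-truth accessor
#' @param x a \code{RatingMatrix}.
#' @return Character vector of true group labels.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "RatingMatrix", function(x) x@truth)

setMethod("show", "SpectralProfile", function(object) {
  cat("SpectralProfile [", object@label, "]\n", sep = "")
  cat("  band weights:",
      paste(sprintf("%s=%.3f", names(object@bandWeights),
                    object@bandWeights), collapse = " "), "\n")
  cat(sprintf("  nominal entropy: %.2f\n", object@entropyLevel))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              ncol(object@samples) / object@fs))
  if (is(object@profile, "SpectralProfile"))
    cat("  synthetic, group ", object@profile@label,
        ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "WindowedFeatures", function(object) {
  cat(sprintf("WindowedFeatures: %d windows\n", length(object@timestamps)))
})

setMethod("show", "SubjectFeatures", function(object) {
  n <- length(object@regions[[1]]@timestamps)
  cat(sprintf(
    "SubjectFeatures '%s': %d regions x %d windows (fs=%g, window=%gs, step=%gs)\n",
    object@subjectId, length(object@regions), n, object@fs,
    object@windowS, object@stepS))
})

setMethod("show", "AudioBuffer", function(object) {
  cat(sprintf("AudioBuffer: %d samples @ %g Hz (%.2f s), peak %.3f\n",
              length(object@samples), object@fs,
              length(object@samples) / object@fs,
              if (length(object@samples)) max(abs(object@samples)) else 0))
})

setMethod("show", "RatingMatrix", function(object) {
  cat(sprintf("RatingMatrix: %d subjects x %d evaluators (%d missing cells)\n",
              nrow(object@ratings), ncol(object@ratings),
              sum(is.na(object@ratings))))
})
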