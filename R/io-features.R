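# Per-subject feature files: a small JSON dialect with subject id,
# acquisition parameters, timestamps and per-region band/entropy arrays.

#' Write a subject feature file
#'
#' Serializes a \code{SubjectFeatures} to UTF-8 JSON with keys
#' \code{subject_id}, \code{acquisition} (\code{fs}, \code{window_s},
#' \code{step_s}), \code{timestamps}, and \code{regions} (per region
#' code: \code{delta}, \code{theta}, \code{alpha}, \code{beta},
#' \code{gamma}, \code{entropy} arrays). Numbers are written at full
#' double precision so write/read round-trips are lossless.
#'
#' @param sf a \code{SubjectFeatures}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(sf, path) {
  stopifnot(is(sf, "SubjectFeatures"))
  regions <- lapply(sf@regions, function(r) {
    out <- lapply(BAND_NAMES, function(b) unname(r@relPower[, b]))
    names(out) <- BAND_NAMES
    out$entropy <- r@entropy
    out
  })
  obj <- list(subject_id = sf@subjectId,
              acquisition = list(fs = sf@fs, window_s = sf@windowS,
                                 step_s = sf@stepS),
              timestamps = sf@regions[[1]]@timestamps,
              regions = regions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

.featNeed <- function(obj, key, where = "top level") {
  if (is.null(obj[[key]]))
    stop("feature file schema violation: missing key '", key,
         "' at ", where)
  obj[[key]]
}

#' Read a subject feature file
#'
#' Parses and validates the JSON dialect written by
#' \code{\link{writeFeatures}}; the first offending key is named on
#' schema violations.
#'
#' @param path feature file path.
#' @return A \code{SubjectFeatures}.
#' @export
readFeatures <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  id <- .featNeed(obj, "subject_id")
  acq <- .featNeed(obj, "acquisition")
  for (k in c("fs", "window_s", "step_s")) .featNeed(acq, k, "acquisition")
  ts <- as.numeric(.featNeed(obj, "timestamps"))
  regs <- .featNeed(obj, "regions")
  missing <- setdiff(REGION_CODES, names(regs))
  if (length(missing))
    stop("feature file schema violation: missing region '",
         missing[1], "'")
  regions <- lapply(REGION_CODES, function(rc) {
    r <- regs[[rc]]
    arrs <- lapply(c(BAND_NAMES, "entropy"), function(k) {
      v <- as.numeric(.featNeed(r, k, paste0("region ", rc)))
      if (length(v) != length(ts))
        stop("feature file schema violation: array length mismatch for '",
             k, "' in region ", rc)
      v
    })
    names(arrs) <- c(BAND_NAMES, "entropy")
    rp <- do.call(cbind, arrs[BAND_NAMES])
    colnames(rp) <- BAND_NAMES
    new("WindowedFeatures", timestamps = ts, relPower = rp,
        entropy = arrs$entropy)
  })
  names(regions) <- REGION_CODES
  new("SubjectFeatures", subjectId = as.character(id),
      fs = as.numeric(acq$fs), windowS = as.numeric(acq$window_s),
      stepS = as.numeric(acq$step_s), regions = regions)
}
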