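# Pipeline configuration: one human-readable YAML file bundling the
# analysis, mapping, montage and synthesis settings.

#' Assemble a pipeline configuration
#'
#' Bundles everything the pipeline needs into one serializable object.
#' The defaults reproduce the published constants exactly (band edges,
#' mapping ranges, window geometry, 48 kHz synthesis).
#'
#' @param analysis an \code{\link{analysisConfig}}.
#' @param mapping a \code{\link{mappingConstants}} list.
#' @param montage channel-to-region table (see
#'   \code{\link{defaultMontage}}).
#' @param synthesisFs audio sampling rate (Hz).
#' @param seed default master seed.
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(analysis = analysisConfig(),
                           mapping = mappingConstants(),
                           montage = defaultMontage(),
                           synthesisFs = 48000, seed = 1) {
  structure(list(analysis = analysis, mapping = mapping,
                 montage = montage, synthesisFs = synthesisFs,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Write a pipeline configuration to YAML
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  mp <- unclass(config$mapping)
  mp$sourceLevels <- as.list(mp$sourceLevels)   # keep band names in YAML
  obj <- list(
    analysis = unclass(config$analysis),
    mapping = mp,
    montage = list(channel = config$montage$channel,
                   region = config$montage$region,
                   weight = config$montage$weight),
    synthesis_fs = config$synthesisFs,
    seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' \code{writeConfig} then \code{readConfig} is the identity;
#' serialize-parse-serialize is a fixed point.
#'
#' @param path YAML file path.
#' @return A \code{\link{pipelineConfig}}.
#' @export
readConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  for (k in c("analysis", "mapping", "montage"))
    if (is.null(obj[[k]])) stop("config is missing the '", k, "' block")
  an <- do.call(analysisConfig, lapply(obj$analysis, unlist))
  mp <- do.call(mappingConstants, lapply(obj$mapping, unlist))
  mo <- data.frame(channel = unlist(obj$montage$channel),
                   region = unlist(obj$montage$region),
                   weight = unlist(obj$montage$weight))
  pipelineConfig(an, mp, mo, synthesisFs = obj$synthesis_fs,
                 seed = obj$seed)
}
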