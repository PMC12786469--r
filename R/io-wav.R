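# Minimal RIFF/WAVE reader and writer: mono PCM16 (default) or IEEE
# float32.

#' Write an AudioBuffer to a WAV file
#'
#' Standard RIFF/WAVE, mono. 16-bit PCM by default; \code{bitDepth = 32}
#' writes IEEE float. Samples outside [-1, 1] are rejected before
#' writing (peak-normalize first).
#'
#' @param audio an \code{AudioBuffer}.
#' @param path output path.
#' @param bitDepth 16 (PCM) or 32 (float).
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(audio, path, bitDepth = 16) {
  stopifnot(is(audio, "AudioBuffer"), bitDepth %in% c(16, 32))
  x <- samples(audio)
  if (length(x) && max(abs(x)) > 1 + 1e-9)
    stop("samples exceed [-1, 1]: refusing to write a clipped file")
  fs <- as.integer(sampleRate(audio))
  bytesPer <- bitDepth / 8
  dataSize <- length(x) * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bitDepth == 16) 1 else 3), con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytesPer), con, size = 4, endian = "little")
  writeBin(as.integer(bytesPer), con, size = 2, endian = "little")
  writeBin(as.integer(bitDepth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bitDepth == 16) {
    writeBin(as.integer(round(pmin(pmax(x, -1), 1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the files \code{\link{writeWav}} produces (mono PCM16 or
#' float32, plain fmt/data chunk layout).
#'
#' @param path WAV file path.
#' @return An \code{AudioBuffer}.
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, raw(), n = sz)
      fmt <- list(
        format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        fs = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt$channels != 1) stop("only mono WAV supported")
      n <- sz / (fmt$bits / 8)
      x <- if (fmt$format == 1 && fmt$bits == 16) {
        readBin(con, integer(), n = n, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else if (fmt$format == 3 && fmt$bits == 32) {
        readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else stop("unsupported WAV encoding")
      return(audioBuffer(x, fmt$fs))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
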