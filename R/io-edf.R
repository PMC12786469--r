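# Minimal EDF (European Data Format) reader/writer: 16-bit records,
# uniform sampling rate, 1-second data records. Enough for lossless
# (up to quantization) round trips of synthetic recordings.

.edfField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write an EEGRecording to an EDF file
#'
#' Writes a standard EDF header plus 16-bit data records of 1 s each
#' (trailing partial seconds are dropped). Physical scaling is set per
#' channel from the data range, so amplitude is preserved to 16-bit
#' precision.
#'
#' @param recording an \code{EEGRecording}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  sm <- samples(recording)
  fs <- as.integer(round(sampleRate(recording)))
  ns <- nrow(sm)
  nRec <- floor(ncol(sm) / fs)
  if (nRec < 1) stop("recording shorter than one 1-second record")
  sm <- sm[, seq_len(nRec * fs), drop = FALSE]
  # scale with the value as printed in the header (6 significant digits)
  # so writer and reader use the identical physical range
  physMax <- as.numeric(sprintf("%.6g",
    pmax(apply(abs(sm), 1, max), 1e-6) * (1 + 1e-6)))
  con <- file(path, "wb")
  on.exit(close(con))
  hdrBytes <- 256L + 256L * ns
  wr <- function(x, width) writeChar(.edfField(x, width), con, eos = NULL)
  wr("0", 8); wr("synthetic subject", 80); wr("synthetic recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(hdrBytes, 8); wr("", 44); wr(nRec, 8); wr("1", 8); wr(ns, 4)
  labs <- channelNames(recording)
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", -physMax[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", physMax[i]), 8)
  for (i in seq_len(ns)) wr("-32767", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- 32767 / physMax
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round(sm[i, cols] * scale[i]))
      writeBin(pmin(pmax(dig, -32768L), 32767L), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

# tolerant 10-20 label normalization: trims blanks, strips an "EEG "
# prefix and reference suffixes, fixes case, maps modern temporal names
.normalizeChannelLabel <- function(lab) {
  s <- gsub("^EEG[ _]*", "", trimws(lab), ignore.case = TRUE)
  s <- gsub("[-_](A1|A2|REF|LE|AVG)$", "", s, ignore.case = TRUE)
  up <- toupper(s)
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  if (up %in% names(alias)) return(unname(alias[up]))
  canon <- tenTwentyChannels()
  hit <- match(up, toupper(canon))
  if (!is.na(hit)) canon[hit] else s
}

#' Read an EDF file
#'
#' Parses the EDF header and 16-bit records, returns physical-unit
#' samples with channel labels normalized to canonical 10-20 names
#' (case/space tolerant; T7/T8/P7/P8 map to T3/T4/T5/T6). All channels
#' must share one sampling rate; resampling is out of scope.
#'
#' @param path EDF file path.
#' @param requireChannels channels that must be present after label
#'   normalization (default the 19-channel 10-20 set); \code{NULL}
#'   disables the check.
#' @return An \code{EEGRecording}.
#' @export
readEDF <- function(path, requireChannels = tenTwentyChannels()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (!nzchar(ver)) stop("unreadable EDF header")
  rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- as.integer(rd(8)); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(nRec) || nRec < 1)
    stop("unreadable EDF header")
  labs <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                # transducer
  for (i in seq_len(ns)) rd(8)                 # dimension
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / recDur
  sm <- matrix(0, nrow = ns, ncol = nRec * spr[1])
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      sm[i, cols] <- physMin[i] + (dig - digMin[i]) * gain[i]
    }
  }
  chans <- vapply(labs, .normalizeChannelLabel, character(1),
                  USE.NAMES = FALSE)
  rownames(sm) <- chans
  if (!is.null(requireChannels)) {
    missing <- setdiff(requireChannels, chans)
    if (length(missing))
      stop("EDF file is missing required channels: ",
           paste(missing, collapse = ", "))
  }
  new("EEGRecording", samples = sm, fs = fs, channelNames = chans,
      profile = NULL, seed = NA_integer_)
}
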