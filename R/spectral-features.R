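# Sliding-window spectral analysis: Welch PSD, relative band powers,
# normalized spectral entropy, and aggregation into topographic regions.

#' Analysis configuration
#'
#' Defaults follow the study conditions: 2 s analysis windows with 1 s step
#' (50\% overlap), Welch estimation inside each window with 1 s Hann
#' segments at 50\% overlap (three averaged segments, 1 Hz resolution),
#' and normalization over the 1--45 Hz total band.
#'
#' @param windowS analysis window length in seconds.
#' @param stepS window step in seconds.
#' @param totalBand length-2 numeric, normalization band in Hz.
#' @param welchSegmentS Welch segment length in seconds.
#' @param welchOverlap Welch segment overlap fraction in [0, 1).
#' @return A list of class \code{AnalysisConfig}.
#' @export
analysisConfig <- function(windowS = 2, stepS = 1, totalBand = c(1, 45),
                           welchSegmentS = 1, welchOverlap = 0.5) {
  stopifnot(windowS > 0, stepS > 0, welchSegmentS > 0,
            welchOverlap >= 0, welchOverlap < 1,
            length(totalBand) == 2, totalBand[1] < totalBand[2])
  structure(list(windowS = windowS, stepS = stepS, totalBand = totalBand,
                 welchSegmentS = welchSegmentS, welchOverlap = welchOverlap),
            class = "AnalysisConfig")
}

#' Default channel-to-region montage
#'
#' Assigns the 19 scalp channels to the 10 topographic regions. Midline
#' channels (Fz, Cz, Pz) contribute with weight 0.5 to the left and right
#' region of their row; all other channels contribute with weight 1 to a
#' single region. The 19-channel set carries no Oz, so the occipital
#' regions hold O1/O2 only.
#'
#' @return A data.frame with columns \code{channel}, \code{region},
#'   \code{weight}. Weights per channel sum to 1.
#' @export
defaultMontage <- function() {
  rbind(
    data.frame(channel = c("Fp1", "F3", "F7", "Fz"), region = "F-L",
               weight = c(1, 1, 1, 0.5)),
    data.frame(channel = c("Fp2", "F4", "F8", "Fz"), region = "F-R",
               weight = c(1, 1, 1, 0.5)),
    data.frame(channel = c("C3", "Cz"), region = "C-L", weight = c(1, 0.5)),
    data.frame(channel = c("C4", "Cz"), region = "C-R", weight = c(1, 0.5)),
    data.frame(channel = c("P3", "Pz"), region = "P-L", weight = c(1, 0.5)),
    data.frame(channel = c("P4", "Pz"), region = "P-R", weight = c(1, 0.5)),
    data.frame(channel = "O1", region = "O-L", weight = 1),
    data.frame(channel = "O2", region = "O-R", weight = 1),
    data.frame(channel = c("T3", "T5"), region = "T-L", weight = c(1, 1)),
    data.frame(channel = c("T4", "T6"), region = "T-R", weight = c(1, 1)))
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

# Periodograms of all Welch segments laid on a global grid: returns
# freqs plus a (bins x nSegments) density matrix and the segment starts
# (0-based samples). Segments are mean-removed and Hann-tapered.
.segmentPeriodograms <- function(x, fs, nseg, segStep) {
  n <- length(x)
  starts <- seq(1L, n - nseg + 1L, by = segStep)
  w <- .hann(nseg)
  scale <- 1 / (fs * sum(w^2))
  idx <- outer(seq_len(nseg) - 1L, starts, "+")
  seg <- matrix(x[idx], nrow = nseg)
  seg <- sweep(seg, 2, colMeans(seg)) * w
  ft <- mvfft(seg)
  nb <- floor(nseg / 2) + 1L
  p <- (Mod(ft[seq_len(nb), , drop = FALSE])^2) * scale
  # one-sided: double interior bins (not DC, not Nyquist when nseg even)
  dbl <- seq(2L, nb - if (nseg %% 2 == 0) 1L else 0L)
  p[dbl, ] <- 2 * p[dbl, ]
  list(freqs = (seq_len(nb) - 1L) * fs / nseg, psd = p,
       starts0 = starts - 1L)
}

#' Welch power spectral density of one analysis window
#'
#' Hann-tapered, mean-removed, 50\%-overlapped segment periodograms are
#' averaged into a one-sided density estimate over [0, fs/2].
#'
#' @param x numeric vector, one channel's samples for a single window
#'   (length \code{windowS * fs}).
#' @param fs sampling rate in Hz.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return A \code{PowerSpectrum}.
#' @examples
#' fs <- 500
#' x <- sin(2 * pi * 10 * seq(0, 2, length.out = 1000))
#' ps <- welchPsd(x, fs, analysisConfig())
#' @export
welchPsd <- function(x, fs, cfg = analysisConfig()) {
  nseg <- round(cfg$welchSegmentS * fs)
  if (length(x) < nseg)
    stop("window shorter than the Welch segment length")
  segStep <- max(1L, round(nseg * (1 - cfg$welchOverlap)))
  pg <- .segmentPeriodograms(x, fs, nseg, segStep)
  new("PowerSpectrum", freqs = pg$freqs, psd = rowMeans(pg$psd))
}

# indicator masks over a frequency grid for band integration
.bandMask <- function(freqs, lo, hi, hiInclusive = FALSE) {
  if (hiInclusive) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
}

.totalMask <- function(freqs, totalBand)
  freqs >= totalBand[1] & freqs <= totalBand[2]

# Vectorized core: psd is a (bins x windows) matrix. Returns list(relPower
# (windows x 5), entropy (windows)).
.featuresFromPsd <- function(freqs, psd, bands, totalBand) {
  tm <- .totalMask(freqs, totalBand)
  if (sum(tm) < 2) stop("fewer than 2 bins inside the total band")
  tot <- colSums(psd[tm, , drop = FALSE])
  if (any(tot <= 0)) stop("degenerate window: total power is zero")
  gammaRow <- which(bands$name == "gamma")
  rp <- vapply(seq_len(nrow(bands)), function(b) {
    m <- .bandMask(freqs, bands$fLo[b], bands$fHi[b],
                   hiInclusive = b == gammaRow)
    colSums(psd[m, , drop = FALSE]) / tot
  }, numeric(ncol(psd)))
  rp <- matrix(rp, ncol = nrow(bands),
               dimnames = list(NULL, bands$name))
  p <- sweep(psd[tm, , drop = FALSE], 2, tot, "/")
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  H <- -colSums(plogp) / log(sum(tm))
  list(relPower = rp, entropy = pmin(pmax(H, 0), 1))
}

#' Relative band powers from a power spectrum
#'
#' Power within each band divided by total power over the normalization
#' band. Band edges are half-open [lo, hi); the gamma upper edge is
#' inclusive, so the five bands exactly tile 1--45 Hz and the fractions
#' sum to 1.
#'
#' @param spec a \code{PowerSpectrum}.
#' @param bands a band table as from \code{\link{eegBands}}.
#' @param totalBand length-2 numeric normalization range in Hz.
#' @return Named numeric vector of 5 fractions summing to 1.
#' @export
relativeBandPowers <- function(spec, bands = eegBands(),
                               totalBand = c(1, 45)) {
  stopifnot(is(spec, "PowerSpectrum"))
  f <- .featuresFromPsd(spec@freqs, matrix(spec@psd, ncol = 1),
                        bands, totalBand)
  drop(f$relPower[1, ])
}

#' Normalized spectral entropy of a power spectrum
#'
#' Shannon entropy (natural log) of the spectrum normalized over the
#' bins inside the total band, divided by log of the bin count, so a
#' single spectral line gives 0 and a flat spectrum gives 1.
#'
#' @inheritParams relativeBandPowers
#' @return A single value in [0, 1].
#' @export
spectralEntropy <- function(spec, totalBand = c(1, 45)) {
  stopifnot(is(spec, "PowerSpectrum"))
  f <- .featuresFromPsd(spec@freqs, matrix(spec@psd, ncol = 1),
                        eegBands(), totalBand)
  f$entropy[1]
}

# PSD time series of one channel: (bins x windows) matrix plus timestamps.
# When the window grid aligns with the Welch segment grid (true for the
# defaults) all segment periodograms are computed once and windows average
# contiguous runs of them; otherwise each window is estimated separately.
.channelPsdSeries <- function(x, fs, cfg) {
  Lw <- round(cfg$windowS * fs)
  Ls <- round(cfg$stepS * fs)
  if (length(x) < Lw) stop("signal shorter than one analysis window")
  nWin <- floor((length(x) - Lw) / Ls) + 1L
  nseg <- round(cfg$welchSegmentS * fs)
  segStep <- max(1L, round(nseg * (1 - cfg$welchOverlap)))
  ts <- (seq_len(nWin) - 1L) * cfg$stepS
  aligned <- Ls %% segStep == 0 && (Lw - nseg) %% segStep == 0
  if (aligned) {
    lastStart <- (nWin - 1L) * Ls + (Lw - nseg)
    pg <- .segmentPeriodograms(x[seq_len(lastStart + nseg)], fs, nseg, segStep)
    perWin <- (Lw - nseg) %/% segStep + 1L
    psd <- vapply(seq_len(nWin), function(i) {
      first <- (i - 1L) * (Ls %/% segStep) + 1L
      rowMeans(pg$psd[, first:(first + perWin - 1L), drop = FALSE])
    }, numeric(length(pg$freqs)))
    list(freqs = pg$freqs, psd = psd, timestamps = ts)
  } else {
    freqs <- NULL
    psd <- vapply(seq_len(nWin), function(i) {
      s0 <- (i - 1L) * Ls
      ps <- welchPsd(x[(s0 + 1L):(s0 + Lw)], fs, cfg)
      freqs <<- ps@freqs
      ps@psd
    }, numeric(floor(nseg / 2) + 1L))
    list(freqs = freqs, psd = psd, timestamps = ts)
  }
}

#' Sliding-window spectral features of a single channel
#'
#' One feature row per window start at 0, stepS, 2 stepS, ...; a trailing
#' partial window is dropped.
#'
#' @param x numeric vector of channel samples.
#' @param fs sampling rate in Hz.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return A \code{WindowedFeatures}.
#' @export
slidingFeatures <- function(x, fs, cfg = analysisConfig()) {
  ser <- .channelPsdSeries(x, fs, cfg)
  f <- .featuresFromPsd(ser$freqs, ser$psd, eegBands(), cfg$totalBand)
  new("WindowedFeatures", timestamps = ser$timestamps,
      relPower = f$relPower, entropy = f$entropy)
}

#' Aggregate per-channel spectra into topographic regions
#'
#' The regional PSD of each window is the weighted mean of its member
#' channels' PSDs (midline channels count 0.5 toward each hemisphere);
#' regional band powers and entropy are then computed from that mean
#' spectrum.
#'
#' @param psdSeries named list (by channel) of PSD series as produced
#'   internally by \code{slidingFeatures}; each element has \code{freqs},
#'   \code{psd} (bins x windows) and \code{timestamps}.
#' @param montage a data.frame with \code{channel}, \code{region},
#'   \code{weight} columns, as \code{\link{defaultMontage}}.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return Named list of \code{WindowedFeatures}, one per region.
#' @export
aggregateRegions <- function(psdSeries, montage = defaultMontage(),
                             cfg = analysisConfig()) {
  regs <- unique(montage$region)
  missing <- setdiff(montage$channel, names(psdSeries))
  if (length(missing))
    stop("montage channels missing from input: ",
         paste(missing, collapse = ", "))
  out <- lapply(regs, function(r) {
    rows <- montage[montage$region == r, , drop = FALSE]
    wsum <- sum(rows$weight)
    if (wsum <= 0) stop("region with zero assigned weight: ", r)
    acc <- 0
    for (k in seq_len(nrow(rows)))
      acc <- acc + rows$weight[k] * psdSeries[[rows$channel[k]]]$psd
    acc <- acc / wsum
    f <- .featuresFromPsd(psdSeries[[rows$channel[1]]]$freqs, acc,
                          eegBands(), cfg$totalBand)
    new("WindowedFeatures",
        timestamps = psdSeries[[rows$channel[1]]]$timestamps,
        relPower = f$relPower, entropy = f$entropy)
  })
  names(out) <- regs
  out
}

#' Extract regional features for one subject
#'
#' Composes the sliding-window Welch analysis and regional aggregation
#' into the per-subject feature container that the synthesiser and the
#' feature-file writer consume.
#'
#' @param recording an \code{EEGRecording}.
#' @param cfg an \code{\link{analysisConfig}}.
#' @param montage channel-to-region table (see \code{\link{defaultMontage}}).
#' @param id subject identifier; defaults to \code{"subject"}.
#' @return A \code{SubjectFeatures}.
#' @export
extractSubject <- function(recording, cfg = analysisConfig(),
                           montage = defaultMontage(), id = "subject") {
  stopifnot(is(recording, "EEGRecording"))
  need <- unique(montage$channel)
  missing <- setdiff(need, channelNames(recording))
  if (length(missing))
    stop("recording is missing montage channels: ",
         paste(missing, collapse = ", "))
  fs <- sampleRate(recording)
  sm <- samples(recording)
  ser <- lapply(need, function(ch)
    .channelPsdSeries(sm[match(ch, channelNames(recording)), ], fs, cfg))
  names(ser) <- need
  regions <- aggregateRegions(ser, montage, cfg)
  new("SubjectFeatures", subjectId = id, fs = fs,
      windowS = cfg$windowS, stepS = cfg$stepS,
      regions = regions[REGION_CODES])
}
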