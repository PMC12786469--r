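# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

bandNamesFx <- c("delta", "theta", "alpha", "beta", "gamma")

# WindowedFeatures with constant band powers / entropy across W windows
constantFeatures <- function(P, H, W = 8) {
  new("WindowedFeatures", timestamps = seq_len(W) - 1,
      relPower = matrix(rep(P, each = W), nrow = W,
                        dimnames = list(NULL, bandNamesFx)),
      entropy = rep(H, W))
}

# SubjectFeatures with the same WindowedFeatures in all 10 regions
uniformSubject <- function(P, H, W = 6, id = "fixture") {
  regs <- lapply(regionCodes(), function(r) constantFeatures(P, H, W))
  names(regs) <- regionCodes()
  new("SubjectFeatures", subjectId = id, fs = 500, windowS = 2,
      stepS = 1, regions = regs)
}

# a 60 s equal-weight synthetic recording (shared across tests)
equalWeightRecording <- function() {
  fixture("eqrec", function() {
    prof <- spectralProfile(
      c(delta = .2, theta = .2, alpha = .2, beta = .2, gamma = .2),
      entropyLevel = 1, label = "control")
    generateRecording(prof, durationS = 60, fs = 500, seed = 1)
  })
}

# mono PowerSpectrum on a 1 Hz grid with a single nonzero bin
oneHotSpectrum <- function(atHz, grid = 0:250) {
  psd <- numeric(length(grid))
  psd[match(atHz, grid)] <- 1
  new("PowerSpectrum", freqs = as.numeric(grid), psd = psd)
}

sineBuffer <- function(freq, durationS = 2, fs = 48000, amp = 0.5) {
  audioBuffer(amp * sin(2 * pi * freq * seq_len(durationS * fs) / fs), fs)
}
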