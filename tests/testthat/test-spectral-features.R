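test_that("Welch PSD locates tones and handles degenerate input", {
  fs <- 500
  t <- seq_len(2 * fs) / fs
  ps <- welchPsd(sin(2 * pi * 10 * t), fs)
  expect_equal(ps@freqs[which.max(ps@psd)], 10)
  ps0 <- welchPsd(numeric(1000), fs)
  expect_true(all(ps0@psd == 0))
  expect_error(welchPsd(numeric(100), fs), "shorter")
})

test_that("Welch PSD of white noise is flat over 1-45 Hz", {
  x <- withr::with_seed(1, rnorm(60 * 500))
  ps <- welchPsd(x, 500)
  sel <- ps@freqs >= 1 & ps@freqs <= 45
  lev <- ps@psd[sel] / mean(ps@psd[sel])
  expect_lt(max(abs(lev - 1)), 0.5)   # ~119 averaged segments
})

test_that("relative band powers integrate the right bins", {
  fs <- 500
  t <- seq_len(2 * fs) / fs
  pAlpha <- relativeBandPowers(welchPsd(sin(2 * pi * 10 * t), fs))
  expect_gt(pAlpha[["alpha"]], 0.98)
  expect_true(all(pAlpha[c("delta", "theta", "beta", "gamma")] < 0.02))
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 20 * t)
  pdb <- relativeBandPowers(welchPsd(x, fs))
  expect_lt(abs(pdb[["delta"]] - 0.5), 0.02)
  expect_lt(abs(pdb[["beta"]] - 0.5), 0.02)
  expect_equal(sum(pdb), 1)
  # gamma upper edge inclusive: a 45 Hz tone is gamma, not lost
  p45 <- relativeBandPowers(welchPsd(sin(2 * pi * 45 * t), fs))
  expect_gt(p45[["gamma"]], 0.95)
  expect_error(relativeBandPowers(welchPsd(numeric(1000), fs)),
               "degenerate")
})

test_that("normalized spectral entropy spans its [0, 1] range", {
  expect_equal(spectralEntropy(oneHotSpectrum(10)), 0)
  flat <- new("PowerSpectrum", freqs = as.numeric(0:250),
              psd = rep(1, 251))
  expect_equal(spectralEntropy(flat), 1)
  x <- withr::with_seed(2, rnorm(1000))
  expect_gt(spectralEntropy(welchPsd(x, 500)), 0.9)
})

test_that("sliding windows follow the 2 s / 1 s grid", {
  fs <- 500
  x <- withr::with_seed(3, rnorm(10 * fs))
  wf <- slidingFeatures(x, fs)
  expect_length(wf@timestamps, 9)          # floor((10-2)/1)+1
  expect_equal(wf@timestamps, 0:8)
  expect_length(slidingFeatures(x[seq_len(2 * fs)], fs)@timestamps, 1)
  expect_error(slidingFeatures(x[1:900], fs), "shorter")
  # stationary input: features constant up to estimation noise. A single
  # channel's 3-segment Welch estimate has ~30% CV per band; averaging
  # the four frontal-left channels brings the SD under 0.05.
  rec <- equalWeightRecording()
  wf2 <- slidingFeatures(samples(rec)[2, ], 500)
  expect_lt(max(apply(relPower(wf2), 2, sd)), 0.12)
  expect_lt(sd(entropyValues(wf2)), 0.05)
  sfS <- extractSubject(rec, id = "stationary")
  expect_lt(max(apply(relPower(regionFeatures(sfS, "F-L")), 2, sd)), 0.05)
})

test_that("sliding analysis equals the direct single-window composition", {
  fs <- 500
  x <- withr::with_seed(4, rnorm(2 * fs))
  wf <- slidingFeatures(x, fs)
  ps <- welchPsd(x, fs)
  expect_equal(drop(relPower(wf)), relativeBandPowers(ps))
  expect_equal(entropyValues(wf), spectralEntropy(ps))
})

test_that("per-window normalization and bounds hold everywhere", {
  rec <- equalWeightRecording()
  sf <- extractSubject(rec, id = "inv")
  for (r in regionCodes()) {
    wf <- regionFeatures(sf, r)
    expect_lt(max(abs(rowSums(relPower(wf)) - 1)), 1e-9)
    expect_true(all(relPower(wf) >= 0 & relPower(wf) <= 1))
    expect_true(all(entropyValues(wf) >= 0 & entropyValues(wf) <= 1))
  }
})

test_that("regional aggregation averages spectra with midline splitting", {
  mont <- defaultMontage()
  # montage audit
  fl <- mont[mont$region == "F-L", ]
  expect_setequal(fl$channel, c("Fp1", "F3", "F7", "Fz"))
  expect_equal(fl$weight[fl$channel == "Fz"], 0.5)
  agg <- stats::aggregate(weight ~ channel, mont, sum)
  expect_true(all(agg$weight == 1))
  expect_setequal(unique(mont$region), regionCodes())
  # identical signals in all channels -> identical regional features
  rec <- equalWeightRecording()
  one <- samples(rec)[1, seq_len(10 * 500)]
  sm <- matrix(rep(one, each = 19), nrow = 19,
               dimnames = list(tenTwentyChannels(), NULL))
  recU <- new("EEGRecording", samples = sm, fs = 500,
              channelNames = tenTwentyChannels(), profile = NULL,
              seed = NA_integer_)
  sfU <- extractSubject(recU, id = "uniform")
  base <- relPower(regionFeatures(sfU, "F-L"))
  for (r in regionCodes())
    expect_equal(relPower(regionFeatures(sfU, r)), base)
  # symmetric central montage: Cz split makes C-L equal C-R
  expect_equal(relPower(regionFeatures(sfU, "C-L")),
               relPower(regionFeatures(sfU, "C-R")))
})

test_that("subject extraction rejects incomplete montages", {
  rec <- generateRecording(controlProfile(), 4, 500, seed = 9,
                           channels = c("C3", "C4"))
  expect_error(extractSubject(rec), "Fp1")
})

test_that("a 120 s recording yields 119 windows per region", {
  rec <- generateRecording(controlProfile(), 120, 500, seed = 21,
                           channels = "Cz")
  wf <- slidingFeatures(samples(rec)[1, ], 500)
  expect_length(wf@timestamps, 119)
})
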