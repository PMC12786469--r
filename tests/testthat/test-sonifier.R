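# a coarse spectral peak finder on a long realization
peakHz <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x - mean(x))[seq_len(n %/% 2)])^2
  (which.max(p) - 1) * fs / n
}

test_that("mapping equations hit the published ranges and bounds", {
  b0 <- c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)
  onehot <- function(b) { v <- b0; v[b] <- 1; v }
  expect_equal(mapFrame(onehot("delta"), 0, detune = 0)$fDelta, 95)
  expect_equal(mapFrame(b0, 0, detune = 0)$fDelta, 45)
  expect_equal(mapFrame(onehot("theta"), 0, detune = 0)$fTheta, 170)
  expect_equal(mapFrame(onehot("alpha"), 0, detune = 0)$fAlpha, 340)
  p <- mapFrame(b0, 0, detune = 0)
  expect_equal(p$qFactor, 11)
  expect_equal(p$fade, 0.15)
  expect_equal(p$tremDepthBeta, 0.1)
  expect_equal(p$tremDepthGamma, 0.15)
  ph <- mapFrame(b0 + 0.5 / 2.5 * c(1, 1, 1, 1, 1) * 0, 1, detune = 0)
  expect_equal(ph$qFactor, 1)
  expect_equal(ph$fade, 1)
  g <- mapFrame(c(delta = .5, theta = .5, alpha = .5, beta = .5,
                  gamma = .5), .5, detune = 0)$gains
  expect_equal(unname(g), rep(0.5^0.85, 5), tolerance = 1e-12)
  expect_error(mapFrame(onehot("delta") * 2, 0), "\\[0, 1\\]")
})

test_that("mapped parameters are monotone and stay in their ranges", {
  set.seed(1)
  prev <- NULL
  for (i in 1:200) {
    P <- setNames(runif(5), c("delta", "theta", "alpha", "beta", "gamma"))
    H <- runif(1)
    p <- mapFrame(P, H)
    expect_true(p$fDelta >= 45 && p$fDelta <= 95)
    expect_true(p$fTheta >= 90 && p$fTheta <= 170)
    expect_true(p$fAlpha >= 180 && p$fAlpha <= 340)
    expect_true(p$qFactor >= 1 && p$qFactor <= 11)
    expect_true(p$fade >= 0.15 && p$fade <= 1)
    expect_true(p$tremDepthBeta >= 0.1 && p$tremDepthBeta <= 0.9)
    expect_true(p$tremDepthGamma >= 0.15 && p$tremDepthGamma <= 0.95)
    expect_lte(abs(p$detuneAlpha), 6 + 14 * H)
    expect_true(all(p$gains >= 0 & p$gains <= 1))
  }
  # monotone in the driving quantity
  f <- vapply(seq(0, 1, .1), function(v)
    mapFrame(c(delta = v, theta = 0, alpha = 0, beta = 0, gamma = 0), 0,
             detune = 0)$fDelta, numeric(1))
  expect_true(all(diff(f) > 0))
  q <- vapply(seq(0, 1, .1), function(h)
    mapFrame(c(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0), h,
             detune = 0)$qFactor, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("sine oscillator is phase continuous at the mapped pitch", {
  fs <- 48000
  x <- oscSine(rep(100, fs), fs)
  expect_equal(peakHz(x, fs), 100, tolerance = 0.51)
  expect_length(oscSine(numeric(0), fs), 0)
  # no clicks: inter-sample jump bounded by the phase increment
  track <- c(rep(100, fs / 2), rep(150, fs / 2))
  y <- oscSine(track, fs)
  expect_lt(max(abs(diff(y))), 2 * pi * 150 / fs * 1.01)
  expect_error(oscSine(c(10, -1), fs), "positive")
})

test_that("triangle oscillator obeys the cent detune law", {
  fs <- 48000
  x <- oscTriangle(rep(250, 8 * fs), 0, fs)
  expect_equal(peakHz(x, fs), 250, tolerance = 0.25)
  x2 <- oscTriangle(rep(250, 8 * fs), 1200, fs)
  expect_equal(peakHz(x2, fs), 500, tolerance = 0.25)
  x3 <- oscTriangle(rep(250, 8 * fs), 20, fs)
  expect_equal(peakHz(x3, fs), 250 * 2^(20 / 1200), tolerance = 0.25)
  expect_true(all(abs(x) <= 1))
})

test_that("pink noise has a ~1/f spectrum and is reproducible", {
  n <- 2^19
  x <- noisePink(n, 48000, seed = 3)
  expect_identical(x, noisePink(n, 48000, seed = 3))
  expect_lt(abs(mean(noisePink(48000, seed = 4))), 0.01)
  ps <- welchPsd(x, 48000,
                 analysisConfig(windowS = n / 48000, stepS = 1,
                                welchSegmentS = 8192 / 48000))
  sel <- ps@freqs >= 100 & ps@freqs <= 8000
  slope <- coef(lm(log(ps@psd[sel]) ~ log(ps@freqs[sel])))[[2]]
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("tremolo modulates amplitude within [1-d, 1]", {
  fs <- 48000
  x <- rep(1, 2 * fs)
  expect_identical(applyTremolo(x, 5, 0, fs), x)
  y <- applyTremolo(x, 5, 1, fs)
  expect_gte(min(y), 0); expect_lte(max(y), 1)
  expect_lt(min(y), 0.01); expect_gt(max(y), 0.99)
  # modulation spectrum of the gain peaks at the tremolo rate
  expect_equal(peakHz(y, fs), 5, tolerance = 0.51)
  expect_error(applyTremolo(x, 5, 1.5, fs), "\\[0, 1\\]")
})

test_that("bit crusher quantizes to the 4-bit grid", {
  expect_equal(bitcrush(0, 4), 0)
  expect_equal(bitcrush(0.3, 4), 0.25)
  x <- withr::with_seed(5, runif(10000, -1.2, 1.2))
  lv <- unique(bitcrush(x, 4))
  expect_lte(length(lv), 17)
  expect_true(all(abs(lv * 8 - round(lv * 8)) < 1e-12))
  expect_error(bitcrush(0.5, 0), "at least 1")
})

test_that("equal-power crossfade interpolates between its inputs", {
  a <- withr::with_seed(6, rnorm(100))
  b <- withr::with_seed(7, rnorm(100))
  expect_identical(crossfade(a, b, 0), a)
  expect_equal(crossfade(a, b, 1), b)
  mid <- crossfade(a, b, 0.5)
  expect_equal(mid, sqrt(2) / 2 * a + sqrt(2) / 2 * b)
  expect_error(crossfade(a, b[1:50], 0.5), "equal length")
})

test_that("exponential ramps reach 99% of the target at 80 ms", {
  fs <- 48000
  expect_equal(rampTrack(c(3, 3, 3), 1, 0.08, fs), rep(3, 3 * fs))
  tr <- rampTrack(c(0, 1), 1, 0.08, fs)
  expect_gte(tr[fs + round(0.08 * fs)], 0.99)
  expect_lt(tr[fs + round(0.04 * fs)], 0.99)
  # monotone during the ramp
  expect_true(all(diff(tr[(fs + 1):(fs + round(.08 * fs))]) > 0))
  # a second step starts from the current value: no discontinuity
  tr2 <- rampTrack(c(0, 1, 0.2), 1, 0.08, fs)
  # per-sample slew of an exponential approach: gap * ln(100) / (rampS*fs)
  expect_lt(max(abs(diff(tr2))), 2 * log(100) / (0.08 * fs))
  expect_error(rampTrack(1:3, 1, 0, fs), "positive")
  expect_error(rampTrack(1:3, 1, 2, fs), "shorter")
})

test_that("silent features render to digital silence", {
  wf <- constantFeatures(c(0, 0, 0, 0, 0), 0.5, W = 3)
  buf <- renderRegion(wf, seed = 1)
  expect_equal(length(samples(buf)), 3 * 48000)
  expect_equal(max(abs(samples(buf))), 0)
})

test_that("region renders are bit-identical under a fixed seed", {
  wf <- constantFeatures(c(.2, .2, .2, .2, .2), 0.8, W = 3)
  b1 <- renderRegion(wf, seed = 33)
  b2 <- renderRegion(wf, seed = 33)
  expect_identical(samples(b1), samples(b2))
  b3 <- renderRegion(wf, seed = 34)
  expect_false(identical(samples(b1), samples(b3)))
})

test_that("the compiled render chain equals the R operator composition", {
  fs <- 48000
  consts <- mappingConstants()
  W <- 3
  P <- matrix(c(.3, .25, .2, .15, .1,
                .1, .2, .3, .25, .15,
                .2, .2, .2, .2, .2), nrow = W, byrow = TRUE,
              dimnames = list(NULL, bandNamesFx))
  H <- c(0.3, 0.7, 0.5)
  wf <- new("WindowedFeatures", timestamps = 0:(W - 1), relPower = P,
            entropy = H)
  seed <- 17
  got <- samples(renderRegion(wf, consts, fs, seed))

  params <- eegsonify:::withSeed(substreamSeed(seed, 101),
    lapply(seq_len(W), function(i) mapFrame(P[i, ], H[i], consts)))
  tk <- function(f) rampTrack(vapply(params, function(p) f(p), numeric(1)),
                              1, consts$rampS, fs)
  n <- W * fs
  delta <- oscSine(tk(function(p) p$fDelta), fs)
  theta <- oscSine(tk(function(p) p$fTheta), fs)
  alpha <- oscTriangle(tk(function(p) p$fAlpha * 2^(p$detuneAlpha / 1200)),
                       0, fs)
  bfB <- signal::butter(2, consts$betaHpCut / (fs / 2), type = "high")
  bfG <- signal::butter(2, consts$gammaHpCut / (fs / 2), type = "high")
  beta <- applyTremolo(
    as.numeric(signal::filter(bfB, noisePink(n, fs, substreamSeed(seed, 102)))),
    tk(function(p) p$tremRateBeta), tk(function(p) p$tremDepthBeta), fs)
  gamma <- applyTremolo(
    as.numeric(signal::filter(bfG, noiseWhite(n, substreamSeed(seed, 103)))),
    tk(function(p) p$tremRateGamma), tk(function(p) p$tremDepthGamma), fs)
  lv <- consts$sourceLevels
  mix <- lv[["delta"]] * tk(function(p) p$gains[["delta"]]) * delta +
         lv[["theta"]] * tk(function(p) p$gains[["theta"]]) * theta +
         lv[["alpha"]] * tk(function(p) p$gains[["alpha"]]) * alpha +
         lv[["beta"]]  * tk(function(p) p$gains[["beta"]])  * beta +
         lv[["gamma"]] * tk(function(p) p$gains[["gamma"]]) * gamma
  faded <- crossfade(mix, bitcrush(mix, consts$bitDepth),
                     tk(function(p) p$fade))
  qTr <- tk(function(p) p$qFactor)
  wet <- pmin(pmax((qTr - consts$q[1]) / consts$q[2], 0), 1)
  bp <- eegsonify:::.biquadBandpassTV(faded, consts$regionBpCenter,
                                      qTr, fs)
  want <- (1 - wet) * faded + wet * bp
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("subject mixes apply focus gains and normalize only on clips", {
  sf <- uniformSubject(c(.25, .25, .2, .2, .1), 0.6, W = 3)
  seed <- 5
  mixAll <- samples(renderSubject(sf, "all", seed = seed))
  expect_length(mixAll, 3 * 48000)
  regions <- lapply(seq_along(regionCodes()), function(ri)
    samples(renderRegion(sf@regions[[regionCodes()[ri]]],
                         seed = substreamSeed(seed, ri))))
  gF <- 10^(-6 / 20); gO <- 10^(-24 / 20)
  wantAll <- Reduce(`+`, lapply(regions, function(r) gF * r))
  if (max(abs(wantAll)) > 1) wantAll <- wantAll * 0.891 / max(abs(wantAll))
  expect_equal(mixAll, wantAll, tolerance = 1e-12)
  mixFoc <- samples(renderSubject(sf, "C-L", seed = seed))
  wantFoc <- 0
  for (ri in seq_along(regionCodes()))
    wantFoc <- wantFoc +
      (if (regionCodes()[ri] == "C-L") gF else gO) * regions[[ri]]
  if (max(abs(wantFoc)) > 1) wantFoc <- wantFoc * 0.891 / max(abs(wantFoc))
  expect_equal(mixFoc, wantFoc, tolerance = 1e-12)
  expect_error(renderSubject(sf, "X-9"), "unknown")
})
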