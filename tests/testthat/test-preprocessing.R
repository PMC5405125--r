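test_that("high-pass removes DC and keeps the passband", {
  fs <- 128
  y <- highpassFilter(rep(100, 4000), fs = fs, nTaps = 513)
  expect_lt(max(abs(y[600:3400])), 1)

  t <- (0:3999) / fs
  x10 <- sin(2 * pi * 10 * t)
  y10 <- highpassFilter(x10, fs = fs, nTaps = 513)
  expect_lt(abs(fittedAmplitude(y10, fs, 10) - 1), 0.01)
})

test_that("stopband attenuation matches the designed response", {
  fs <- 64
  b <- designHighpass(fs, cutoffHz = 1, transitionHz = 0.2)
  t <- (0:(fs * 120 - 1)) / fs
  x <- sin(2 * pi * 0.1 * t)
  y <- highpassFilter(x, fs = fs)
  measured <- fittedAmplitude(y, fs, 0.1, trim = 0.3)
  designed <- Mod(firFrequencyResponse(b, 0.1, fs))
  expect_lt(abs(measured - designed), 0.01)
  # roughly half-gain at the cutoff (fir1 rescales the band edge a little),
  # flat above the transition
  expect_gt(Mod(firFrequencyResponse(b, 1, fs)), 0.4)
  expect_lt(Mod(firFrequencyResponse(b, 1, fs)), 0.7)
  gainAbove <- Mod(firFrequencyResponse(b, c(1.2, 2, 5, 10), fs))
  expect_true(all(abs(20 * log10(gainAbove)) < 0.5))
})

test_that("filters are linear", {
  fs <- 128
  set.seed(1)
  a <- rnorm(2000); b <- rnorm(2000)
  fa <- highpassFilter(a, fs = fs, nTaps = 257)
  fb <- highpassFilter(b, fs = fs, nTaps = 257)
  fab <- highpassFilter(a + b, fs = fs, nTaps = 257)
  expect_equal(fab, fa + fb, tolerance = 1e-9)
})

test_that("notch removes mains and harmonics, spares neighbours", {
  fs <- 512
  t <- (0:(8 * fs - 1)) / fs
  y60 <- notchLineNoise(sin(2 * pi * 60 * t), lineFreq = 60, fs = fs)
  expect_lt(fittedAmplitude(y60, fs, 60), 0.03)
  y120 <- notchLineNoise(sin(2 * pi * 120 * t), lineFreq = 60, fs = fs)
  expect_lt(fittedAmplitude(y120, fs, 120), 0.03)
  y10 <- notchLineNoise(sin(2 * pi * 10 * t), lineFreq = 60, fs = fs)
  expect_lt(abs(fittedAmplitude(y10, fs, 10) - 1), 0.01)
  expect_equal(max(abs(notchLineNoise(numeric(4000), 60, fs = fs))), 0)
  expect_error(notchLineNoise(numeric(100), lineFreq = 300, fs = 512),
               "Nyquist")
})

test_that("method-1 flags the classic pathologies with reasons", {
  set.seed(8)
  fs <- 128
  n <- fs * 20
  common <- rnorm(n)                      # shared cortical-like signal
  data <- matrix(rnorm(16 * n, sd = 3), 16) + 15 * rbind(matrix(
    rep(common, each = 15), 15), 0)
  data[16, ] <- rnorm(n, sd = 3)          # uncorrelated with neighbours
  data[1, ] <- 0                          # flat channel
  data[2, ] <- data[2, ] * 120            # huge range
  data[3, seq(1, n, by = 300)] <- 400     # spiky: kurtosis outlier
  rec <- EEGRecording(data, fs, positions = sensorLayout(16))
  # few channels: the robust (median/MAD) kurtosis z-score is the one that
  # can exceed 5 here (a mean/SD z over n channels is bounded by (n-1)/sqrt(n))
  dec <- rejectChannelsMethod1(rec, robustKurtosis = TRUE)
  expect_true("LOW_RANGE" %in% dec@reasons[[1]])
  expect_true("HIGH_RANGE" %in% dec@reasons[[2]])
  expect_true("KURTOSIS" %in% dec@reasons[[3]])
  expect_true("NEIGHBOR_CORR" %in% dec@reasons[[16]])
})

test_that("method-1 decisions are permutation invariant", {
  out <- tinyWalking(nChannels = 12, nCycles = 20, seed = 5)
  rec <- out$recording
  perm <- c(7, 3, 11, 1, 9, 5, 12, 2, 10, 4, 8, 6)
  permRec <- EEGRecording(eegData(rec)[perm, ], samplingRate(rec),
                          labels = channelLabels(rec)[perm],
                          positions = sensorPositions(rec)[perm, ])
  a <- rejectChannelsMethod1(rec)
  b <- rejectChannelsMethod1(permRec)
  expect_equal(a@flagged[perm], b@flagged)
})

test_that("homogeneous channels are rarely false-flagged", {
  # i.i.d. equal-variance channels carry none of the pathologies the
  # kurtosis and SD criteria hunt; neighbour correlation is skipped
  # (no positions) because white noise is legitimately uncorrelated
  flags <- vapply(1:20, function(seed) {
    set.seed(seed)
    rec <- EEGRecording(matrix(rnorm(64 * 2000, sd = 20), 64), fs = 128)
    dec <- suppressWarnings(rejectChannelsMethod1(rec))
    sum(dec@flagged)
  }, numeric(1))
  expect_lte(mean(flags), 2)
})
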