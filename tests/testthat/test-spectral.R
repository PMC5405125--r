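# independent oracle: fraction of a unit sinusoid's power landing in each
# band, from the analytic Hamming-window kernel |W(f -/+ f0)|^2 sampled at
# the zero-padded bin frequencies (no Welch machinery involved)
lineAllocationOracle <- function(f0, fs, bands) {
  L <- round(0.512 * fs); nfft <- round(1.024 * fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  W2 <- function(f) Mod(vapply(f, function(ff)
    sum(w * exp(-2i * pi * ff * (0:(L - 1)) / fs)), complex(1)))^2
  fbin <- (0:(nfft %/% 2)) * fs / nfft
  p <- W2(fbin - f0) + W2(fbin + f0)
  alloc <- vapply(bands, function(b)
    sum(p[fbin >= b[1] & fbin < b[2]]), numeric(1))
  alloc / sum(p)
}

test_that("band power matches the window-kernel line allocation", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  bp <- bandAbsolutePower(sin(2 * pi * 10 * t), fs)
  expect_gte(bp[["alpha"]] / sum(bp), 0.95)
  oracle10 <- lineAllocationOracle(10, fs, eegBands())
  expect_equal(unname(bp / sum(bp)), unname(oracle10 / sum(oracle10)),
               tolerance = 0.02)

  # two equal lines: measured delta/beta ratio equals the kernel-predicted
  # ratio (delta loses a few % of its line below the 1 Hz edge)
  bp2 <- bandAbsolutePower(sin(2 * pi * 3 * t) + sin(2 * pi * 25 * t), fs)
  o3 <- lineAllocationOracle(3, fs, eegBands())
  o25 <- lineAllocationOracle(25, fs, eegBands())
  expect_equal(bp2[["delta"]] / bp2[["beta"]],
               o3[["delta"]] / o25[["beta"]], tolerance = 0.05)
  expect_lt((bp2[["theta"]] + bp2[["gamma"]]) / sum(bp2), 0.05)
})

test_that("white-noise band power is proportional to bandwidth", {
  fs <- 256
  ratios <- sapply(1:20, function(seed) {
    set.seed(seed)
    bp <- bandAbsolutePower(rnorm(fs * 12), fs)
    widths <- vapply(eegBands(), diff, numeric(1))
    (bp / sum(bp)) / (widths / sum(widths))
  })
  expect_true(all(abs(rowMeans(ratios) - 1) < 0.10))
})

test_that("band powers respect Parseval for band-limited input", {
  fs <- 256
  set.seed(3)
  # pink-ish band-limited input built from in-band sinusoids
  t <- (0:(fs * 16 - 1)) / fs
  freqs <- c(2.5, 6, 11, 22, 45)
  x <- rowSums(sapply(freqs, function(f)
    sin(2 * pi * f * t + runif(1, 0, 2 * pi)) / f^0.5))
  bp <- bandAbsolutePower(x, fs)
  total <- var(x)
  expect_lte(sum(bp), total * 1.1)
  expect_lt(abs(sum(bp) - total) / total, 0.10)
})

test_that("median band-power summary ignores channel order", {
  out <- tinyWalking(nChannels = 6, nCycles = 15, seed = 2)
  rec <- out$recording
  perm <- c(4, 1, 6, 3, 5, 2)
  recP <- EEGRecording(eegData(rec)[perm, ], samplingRate(rec))
  expect_equal(medianBandPower(rec), medianBandPower(recP))
})

test_that("gait-locked amplitude maps expose the contact transient", {
  out <- tinyWalking(nChannels = 8, nCycles = 40, artifactChannels = 1:2,
                     seed = 5, artifactAmpUv = 60)
  rec <- out$recording

  silent <- EEGRecording(matrix(0, 2, nSamples(rec)), samplingRate(rec))
  m0 <- gaitLockedAmplitudeMap(silent, out$events, 1)
  expect_equal(max(abs(m0@map)), 0)

  m <- gaitLockedAmplitudeMap(rec, out$events, 1)
  base <- m@meanTrace[m@time < -0.05]
  transient <- mean(m@meanTrace[m@time >= 0.02 & m@time <= 0.1])
  expect_gt(transient, mean(base) + 3 * sd(base))
  expect_true(nrow(m@map) %in% 38:40)   # one row per event window that fits

  # event-shuffled control: no aligned transient
  set.seed(9)
  len <- nSamples(rec)
  fake <- sort(sample.int(len - 400, 40)) + 50
  mS <- gaitLockedAmplitudeMap(rec, fake, 1)
  baseS <- mS@meanTrace[mS@time < -0.05]
  transS <- mean(mS@meanTrace[mS@time >= 0.02 & mS@time <= 0.1])
  expect_lt(transS, mean(baseS) + 1.5 * sd(baseS))
})
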