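test_that("gait-locked activations score high, phase-random ones low", {
  d <- makeDecomposition(seed = 2)
  fr <- tcrScoreComponents(d$ic, d$events)
  expect_gt(fr[1], 0.9)                      # artifact component
  # a cycle-repeating activation scores a full fraction
  fs <- 256
  cyc <- sin(2 * pi * (0:511) / 512)
  act <- rbind(rep(cyc, 20))
  ic <- ICSet(act, matrix(1, 1, 1), fs = fs)
  ev <- GaitEvents(seq(0, by = 512, length.out = 20))
  expect_equal(unname(tcrScoreComponents(ic, ev)), 1.0)

  # oscillations phase-random w.r.t. the events stay near chance
  frOsc <- vapply(1:5, function(s) {
    dd <- makeDecomposition(seed = s + 10)
    mean(tcrScoreComponents(dd$ic, dd$events)[2:3])
  }, numeric(1))
  expect_lt(mean(frOsc), 0.2)
})

test_that("the artifact component outscores all others across seeds", {
  wins <- vapply(1:12, function(s) {
    d <- makeDecomposition(seed = s)
    which.max(tcrScoreComponents(d$ic, d$events)) == 1
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("spectral peaks qualify only in alpha/beta/gamma", {
  f <- seq(1, 100, by = 0.5)
  bg <- 100 / f                              # aperiodic 1/f background
  peak <- function(f0, db = 6) bg * 10^(db / 10 * exp(-(f - f0)^2 / 8))
  p25 <- detectSpectralPeak(f, peak(25))
  expect_true(p25$neural)
  expect_equal(p25$band, "beta")
  expect_equal(p25$freqHz, 25, tolerance = 0.1)
  expect_false(detectSpectralPeak(f, bg)$neural)
  expect_false(detectSpectralPeak(f, peak(3))$neural)  # delta does not count
})

test_that("component spectra expose the oscillatory sources", {
  d <- makeDecomposition(seed = 4)
  psd <- componentPsd(d$ic)
  p10 <- detectSpectralPeak(psd$freq, psd$power[2, ])
  p25 <- detectSpectralPeak(psd$freq, psd$power[3, ])
  expect_true(p10$neural); expect_equal(p10$band, "alpha")
  expect_true(p25$neural); expect_equal(p25$band, "beta")
  expect_false(detectSpectralPeak(psd$freq, psd$power[1, ])$neural)
})

test_that("scalp-map smoothness separates smooth from scrambled maps", {
  pos <- sensorLayout(64)
  expect_equal(scalpMapSmoothness(rep(2, 64), pos), 1.0)
  delta <- c(1, rep(0, 63))
  expect_lt(scalpMapSmoothness(delta, pos), 0.76)  # below the default cutoff
  g <- exp(-((pos[, 1] - 0.2)^2 + (pos[, 2] - 0.3)^2) / (2 * 0.4^2))
  set.seed(6)
  for (i in 1:10)
    expect_gt(scalpMapSmoothness(g, pos),
              scalpMapSmoothness(sample(g), pos))
})

test_that("component selection retains neural evidence", {
  p <- tcrParams()
  fr <- c(0.9, 0.9, 0.5)
  peaks <- list(list(neural = FALSE, band = NA, freqHz = NA,
                     prominenceDb = NA),
                list(neural = TRUE, band = "beta", freqHz = 25,
                     prominenceDb = 6),
                list(neural = FALSE, band = NA, freqHz = NA,
                     prominenceDb = NA))
  dec <- selectComponents(fr, peaks, smoothness = c(0.3, 0.3, 0.3),
                          params = p)
  expect_equal(dec@flagged, c(TRUE, FALSE, FALSE))
  expect_true(dec@evidence$neuralEvidence[2])
  # a smooth dipolar-looking map also counts as neural evidence
  dec2 <- selectComponents(fr, c(FALSE, FALSE, FALSE),
                           smoothness = c(0.95, 0.3, 0.3), params = p)
  # comp 1 rescued by its smooth map; comp 2 has no neural evidence at all
  expect_equal(dec2@flagged, c(FALSE, TRUE, FALSE))
})

test_that("back-projection removal is exact and targeted", {
  d <- makeDecomposition(seed = 3)
  # no flags: identity
  same <- removeComponentsAndBackproject(d$rec, d$ic, integer())
  expect_equal(eegData(same), eegData(d$rec), tolerance = 1e-10)
  # all flagged: the decomposition subspace vanishes
  zero <- removeComponentsAndBackproject(d$rec, d$ic, seq_len(d$nComp))
  expect_lt(max(abs(eegData(zero))), 1e-8)
  # removing never increases total variance here
  one <- removeComponentsAndBackproject(d$rec, d$ic, 1L)
  expect_lte(sum(eegData(one)^2), sum(eegData(d$rec)^2))
})

test_that("removing the artifact component cleans artifact channels only", {
  d <- makeDecomposition(seed = 5)
  cleaned <- removeComponentsAndBackproject(d$rec, d$ic, 1L)
  artCh <- order(d$ic@mixing[, 1], decreasing = TRUE)[1:2]
  quietCh <- which(abs(d$ic@mixing[, 1]) < 0.02)
  postContact <- function(rec, ch) {
    m <- gaitLockedAmplitudeMap(rec, d$events, ch,
                                windowSec = c(-0.2, 0.4))
    mean(m@meanTrace[m@time >= 0 & m@time <= 0.1])
  }
  for (ch in artCh[1:2])
    expect_lt(postContact(cleaned, ch), 0.5 * postContact(d$rec, ch))
  for (ch in quietCh) {
    v0 <- var(eegData(d$rec)[ch, ])
    v1 <- var(eegData(cleaned)[ch, ])
    expect_lt(abs(v1 - v0) / v0, 0.05)
  }
})

test_that("unmixing-based construction inverts consistently", {
  set.seed(8)
  W <- matrix(rnorm(16), 4)                   # square unmixing
  rec <- EEGRecording(matrix(rnorm(4 * 600), 4), fs = 200)
  ic <- icSetFromUnmixing(rec, W)
  expect_equal(ic@mixing %*% ic@activations, eegData(rec),
               tolerance = 1e-10)
  expect_error(ICSet(matrix(0, 2, 10), matrix(0, 3, 2),
                     unmixing = matrix(1, 2, 3), fs = 100), "identity")
})
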