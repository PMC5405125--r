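test_that("moving-average smoothing matches window enumeration", {
  y <- smoothMovingAverage(rep(3.5, 1000), fs = 512)
  expect_true(all(y == 3.5))
  expect_equal(attr(y, "window"), 51)    # 100 ms at 512 Hz
  expect_equal(attr(y, "step"), 26)      # 50 ms at 512 Hz

  # unit impulse: exactly the windows covering the impulse read 1/51
  x <- numeric(1024); x[301] <- 1        # 0-based sample 300
  y <- smoothMovingAverage(x, fs = 512)
  starts <- (seq_along(y) - 1) * 26
  covered <- starts <= 300 & 300 <= starts + 50
  expect_equal(as.numeric(y), ifelse(covered, 1 / 51, 0))

  # linear ramp: window means equal the ramp at the window centres
  r <- seq(0, 1, length.out = 1024)
  yr <- smoothMovingAverage(r, fs = 512)
  centers <- starts[seq_along(yr)] + (51 - 1) / 2
  expect_equal(as.numeric(yr), centers / 1023, tolerance = 1e-12)
})

test_that("epochs warp to the common length preserving shape", {
  # identity warp
  x <- rnorm(1000)
  es <- epochAndWarp(x, c(0, 1000), warpPoints = 1000)
  expect_equal(epochArray(es)[1, , 1], x)

  # a 500-point ramp stays a ramp after warping
  es <- epochAndWarp(seq(0, 1, length.out = 600), c(0, 500),
                     warpPoints = 1000)
  w <- epochArray(es)[1, , 1]
  ideal <- seq(0, 499 / 599, length.out = 1000)
  expect_lt(max(abs(w - ideal)), 1e-9)

  # single-cycle sinusoids of random lengths align in phase after warping
  set.seed(2)
  lens <- sample(400:900, 8)
  ev <- c(0, cumsum(lens))
  x <- unlist(lapply(lens, function(L) sin(2 * pi * (0:(L - 1)) / L)))
  es <- epochAndWarp(x, ev, warpPoints = 1000)
  w <- epochArray(es)[, , 1]
  cors <- cor(t(w))
  expect_gt(min(cors), 0.999)
})

test_that("template is the across-epoch mean and concentrates as 1/sqrt(n)", {
  E <- matrix(rep(sin(1:100 / 5), 3), 3, byrow = TRUE)
  expect_equal(computeTemplate(E), sin(1:100 / 5))
  expect_equal(computeTemplate(rbind(E[1, ], -E[1, ])), numeric(100))

  set.seed(5)
  s <- sin(seq(0, 4 * pi, length.out = 200))
  E <- matrix(rep(s, each = 500), 500) + matrix(rnorm(500 * 200), 500)
  tmpl <- computeTemplate(E)
  expect_gte(mean(abs(tmpl - s) <= 4 / sqrt(500)), 0.99)
})

test_that("epoch-template correlations are exact Pearson with 0 sentinel", {
  set.seed(3)
  tm <- rnorm(1000)
  E <- rbind(tm, 3 * tm + 7, -tm, rnorm(1000), rep(2, 1000))
  r <- epochTemplateCorrelations(E, tm)
  expect_equal(r[1:3], c(1, 1, -1), tolerance = 1e-12)
  expect_equal(r[4], pearsonOracle(E[4, ], tm), tolerance = 1e-12)
  expect_equal(r[5], 0)                   # zero-variance epoch sentinel

  # oracle equivalence on an EpochSet
  out <- tinyWalking(nChannels = 4, nCycles = 15, seed = 1)
  es <- epochAndWarp(smoothMovingAverage(out$recording), out$events)
  tmpl <- computeTemplate(es)
  corr <- epochTemplateCorrelations(es, tmpl)
  for (ch in 1:4) for (i in c(1, 7, 14))
    expect_equal(unname(corr[i, ch]),
                 pearsonOracle(epochArray(es)[i, , ch], tmpl[, ch]),
                 tolerance = 1e-12)
})

test_that("warped-noise correlations match a permutation null", {
  # ~24 effective values upsampled to 1,000 points, as after smoothing a
  # 1.2 s cycle: the |r| distribution must match permuting those values
  set.seed(7)
  nEff <- 24
  draw <- function(v) approx(seq_len(nEff), v, n = 1000)$y
  robs <- replicate(1500, cor(draw(rnorm(nEff)), draw(rnorm(nEff))))
  base <- rnorm(nEff); tmplW <- draw(rnorm(nEff))
  rperm <- replicate(1500, cor(draw(sample(base)), tmplW))
  D <- suppressWarnings(ks.test(abs(robs), abs(rperm)))$statistic
  expect_lt(D, 0.05)
})

test_that("fraction of correlated epochs uses the signed rule", {
  expect_equal(fractionCorrelated(c(0.5, 0.3, 0.45, 0.41), 0.4), 0.75)
  expect_equal(fractionCorrelated(rep(-0.9, 10), 0.4), 0)
  m <- cbind(a = c(0.5, 0.1), b = c(0.9, 0.9))
  expect_equal(fractionCorrelated(m), c(a = 0.5, b = 1))
})

test_that("amplitude range averages per-window ranges", {
  expect_equal(amplitudeRange(matrix(5, 3, 1000)), 0)

  ramp <- matrix(seq(0, 10, length.out = 1000), 1)
  expect_equal(amplitudeRange(ramp), 10 * 99 / 999, tolerance = 1e-12)

  spike <- matrix(0, 1, 1000); spike[1, 500] <- 10
  expect_equal(amplitudeRange(spike), 1.0)   # vs 10 for a whole-epoch range
  expect_equal(diff(range(spike)), 10)
})

test_that("breaking point matches exhaustive chord-distance search", {
  v1 <- c(rep(5, 10), 10, 20, 30, 40, 50)
  bp <- findBreakingPoint(v1)
  expect_equal(bp$index, kneeOracle(v1))

  expect_true(is.na(findBreakingPoint(1:50)$index))

  x <- seq(0, 1, length.out = 1001)
  bp <- findBreakingPoint(x^2)
  expect_equal((bp$index - 1) / 1000, 0.5, tolerance = 2e-3)
  expect_equal(bp$value, 0.25, tolerance = 2e-3)

  set.seed(9)
  for (i in 1:25) {
    v <- sort(rexp(sample(5:60, 1))^sample(1:3, 1))
    expect_equal(findBreakingPoint(v)$index, kneeOracle(v))
  }
  expect_error(findBreakingPoint(c(1, 2, 3)), "at least 5")
})

test_that("surrogate event sets honour sector stratification", {
  se <- generateSurrogateEvents(20000, 512, nCycles = 20, seed = 3)
  expect_equal(length(se@sets), 10)
  counts <- table(findInterval(eventTimes(se@sets[[1]]),
                               seq(0, 20000, length.out = 6),
                               rightmost.closed = TRUE))
  expect_equal(as.numeric(counts), rep(2, 5))   # 10 events, 2 per sector

  se2 <- generateSurrogateEvents(20000, 512, nCycles = 20, seed = 3)
  expect_identical(lapply(se2@sets, eventTimes), lapply(se@sets, eventTimes))

  big <- generateSurrogateEvents(1e6, 512, nCycles = 1000, seed = 1)
  ct <- table(findInterval(eventTimes(big@sets[[1]]),
                           seq(0, 1e6, length.out = 6),
                           rightmost.closed = TRUE))
  expect_equal(as.numeric(ct), rep(100, 5))
  expect_true(all(eventTimes(big@sets[[1]]) < 1e6))

  expect_error(generateSurrogateEvents(1000, 512, nCycles = 100, seed = 1,
                                       epochLenSamples = 100),
               "infeasible")
})

test_that("distribution intersection recovers the analytic crossing", {
  set.seed(21)
  est <- estimateCorrelationThreshold(rnorm(1e5, 0.6, 0.1),
                                      rnorm(1e5, 0.0, 0.1))
  expect_false(est$noSeparation)
  expect_equal(est$rStar, 0.30, tolerance = 0.02 / 0.30)

  x <- rnorm(5000, 0, 0.15)
  expect_true(estimateCorrelationThreshold(x, x)$noSeparation)
  expect_error(estimateCorrelationThreshold(rnorm(50), rnorm(500)),
               "at least 100")
})

test_that("strong artifacts separate experimental from surrogate nulls", {
  out <- tinyWalking(nChannels = 16, nCycles = 120, artifactChannels = 1:4,
                     seed = 13, artifactAmpUv = 60)
  rec <- highpassFilter(out$recording)
  st <- tcrChannelStats(rec, out$events)
  sur <- tcrSurrogateStats(rec, nCycles = 120, seed = 5)
  est <- estimateCorrelationThreshold(as.vector(st@corr), sur$correlations)
  expect_false(est$noSeparation)
  # the crossing sits right of the null bulk and left of the artifact mass
  expect_gt(est$rStar, quantile(sur$correlations, 0.5))
  expect_lt(est$rStar, median(st@corr[, 1:4]))
})

test_that("the pipeline is equivariant under common rescaling", {
  out <- tinyWalking(nChannels = 8, nCycles = 25, seed = 4)
  rec <- out$recording
  recS <- EEGRecording(3.7 * eegData(rec), samplingRate(rec),
                       labels = channelLabels(rec))
  a <- tcrChannelStats(rec, out$events)
  b <- tcrChannelStats(recS, out$events)
  expect_equal(b@corr, a@corr, tolerance = 1e-12)
  expect_identical(b@fraction, a@fraction)
  expect_equal(b@arng, 3.7 * a@arng, tolerance = 1e-12)
  expect_equal(b@breakingValue, 3.7 * a@breakingValue, tolerance = 1e-12)
  expect_equal(b@breakingIndex, a@breakingIndex)
})

test_that("channel selection is the conjunction with cross-condition union", {
  p <- tcrParams()
  A <- fakeStats(fraction = c(0.80, 0.90, 0.95, 0.10),
                 arng = c(30, 5, 30, 30), breakingValue = 20)
  B <- fakeStats(fraction = c(0.80, 0.90, 0.10, 0.10),
                 arng = c(30, 5, 5, 30), breakingValue = 20,
                 condition = "B")
  dec <- selectChannelsTcr(A, B, p)
  # 1: criteria met in both; 2: fraction high but ARNG below the knee;
  # 3: criteria met only in A, still removed from both; 4: low fraction
  expect_equal(dec@flagged, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(dec@evidence$flaggedA, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(dec@evidence$flaggedB, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(dec@reasons[[3]], "TCR")

  expect_warning(selectChannelsTcr(A, NULL, p), "single-condition")
  Bbad <- fakeStats(c(0.5, 0.5), c(1, 1), 2)
  expect_error(selectChannelsTcr(A, Bbad, p), "channel set")
})

test_that("warped epochs always have the exact common length", {
  out <- tinyWalking(nChannels = 3, nCycles = 18, seed = 10)
  for (wp in c(100L, 500L, 1000L)) {
    es <- epochAndWarp(smoothMovingAverage(out$recording), out$events,
                       warpPoints = wp)
    expect_equal(dim(epochArray(es))[2], wp)
    expect_equal(nEpochs(es), 17)
  }
  corr <- epochTemplateCorrelations(
    epochAndWarp(smoothMovingAverage(out$recording), out$events))
  expect_true(all(corr >= -1 & corr <= 1))
})
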