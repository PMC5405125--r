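# Small fixtures and independent oracles shared across test files.

# compact walking fixture: few channels, short recording
tinyWalking <- function(nChannels = 16, nCycles = 40, artifactChannels = 1:2,
                        fs = 256, seed = 1, artifactAmpUv = 40, ...) {
  generateWalkingEEG(synthConfig(
    nChannels = nChannels, fs = fs, nCycles = nCycles,
    artifactChannels = artifactChannels, artifactAmpUv = artifactAmpUv,
    seed = seed, ...))
}

# brute-force knee oracle: exhaustive point-to-chord distance on the
# normalised curve, computed from the full two-point line formula
kneeOracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (v[n] == v[1]) return(NA_integer_)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - v[1]) / (v[n] - v[1])
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  if (max(d) < 1e-9) return(NA_integer_)
  which.max(d)
}

# direct Pearson correlation from covariance/variance definitions
pearsonOracle <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# amplitude of a sinusoid at freqHz fitted by least squares (mid-section)
fittedAmplitude <- function(x, fs, freqHz, trim = 0.2) {
  n <- length(x)
  idx <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  t <- (idx - 1) / fs
  fit <- lm(x[idx] ~ sin(2 * pi * freqHz * t) + cos(2 * pi * freqHz * t))
  sqrt(sum(coef(fit)[2:3]^2))
}

# minimal TcrChannelStats for decision-rule tests
fakeStats <- function(fraction, arng, breakingValue, condition = "A",
                      params = tcrParams()) {
  labs <- paste0("E", seq_along(fraction))
  new("TcrChannelStats", condition = condition,
      corr = matrix(0, 1, length(fraction),
                    dimnames = list(NULL, labs)),
      fraction = setNames(fraction, labs),
      arng = setNames(arng, labs),
      breakingIndex = 1L, breakingValue = breakingValue,
      params = params)
}

# known decomposition: sources (rows) mixed into channels.  comp 1 carries
# the heel-strike artifact (slow transients, power below ~8 Hz), comps 2-3
# genuine oscillations with random waxing envelopes, the rest white noise.
makeDecomposition <- function(seed = 1, nChannels = 16, nCycles = 40,
                              fs = 256) {
  set.seed(seed)
  onsets <- round(0.5 * fs) + round(cumsum(c(0, rnorm(nCycles - 1, 1.2,
                                                      0.1))) * fs)
  n <- max(onsets) + round(1.5 * fs)
  t <- (0:(n - 1)) / fs
  art <- numeric(n)
  for (o in onsets) {
    idx <- o + seq_len(round(0.4 * fs))
    idx <- idx[idx <= n]
    tt <- (seq_along(idx) - 1) / fs
    art[idx] <- art[idx] + exp(-(tt - 0.05)^2 / (2 * 0.04^2))
  }
  envelope <- function() {
    w <- round(0.5 * fs)
    z <- stats::filter(rnorm(n + 2 * w), rep(1 / w, w), sides = 2)
    z <- z[w + seq_len(n)]
    1 + 0.5 * (z - mean(z)) / sd(z)
  }
  nComp <- 6
  S <- rbind(
    art * 15,
    sin(2 * pi * 10 * t + runif(1, 0, 2 * pi)) * envelope(),
    sin(2 * pi * 25 * t + runif(1, 0, 2 * pi)) * envelope(),
    matrix(rnorm(3 * n), 3))
  pos <- sensorLayout(nChannels)
  smoothMap <- function(cx, cy, w = 0.4)
    exp(-((pos[, 1] - cx)^2 + (pos[, 2] - cy)^2) / (2 * w^2))
  M <- cbind(smoothMap(-0.6, 0.6, 0.35),        # artifact: compact patch
             smoothMap(0, 0.5), smoothMap(0.3, -0.3),
             matrix(rnorm(nChannels * 3), nChannels))
  rec <- EEGRecording(M %*% S, fs, positions = pos, condition = "walking")
  list(rec = rec, ic = ICSet(S, M, fs = fs),
       events = GaitEvents(onsets, "RHS"), nComp = nComp, pos = pos)
}
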