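#' @include AllClasses.R
NULL

#' Configure the synthetic walking-EEG generator
#'
#' Builds a [SynthConfig-class].  The defaults emulate a high-density
#' treadmill-walking recording: 256 channels at 512 Hz, gait cycles of
#' 1.2 +/- 0.1 s, pink background noise of 10 uV RMS, 10 Hz and 25 Hz
#' oscillatory sources with smooth disc topographies, and a 40 uV
#' heel-strike-locked artifact on ten channels.
#'
#' @param nChannels,fs,nCycles,cycleMeanS,cycleSdS see [SynthConfig-class].
#' @param artifactChannels,artifactAmpUv,artifactJitterMs see
#'   [SynthConfig-class].
#' @param neuralSources list of \code{list(freqHz, ampUv, center, width)};
#'   \code{center} is on the unit sensor disc.
#' @param noiseExponent,noiseRmsUv,lineFreq,lineAmpUv see [SynthConfig-class].
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return A [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nChannels = 16, nCycles = 12, seed = 7)
#' @export
synthConfig <- function(nChannels = 256L, fs = 512, nCycles = 100L,
                        cycleMeanS = 1.2, cycleSdS = 0.1,
                        artifactChannels = 1:10, artifactAmpUv = 40,
                        artifactJitterMs = 10,
                        neuralSources = list(
                          list(freqHz = 10, ampUv = 5,
                               center = c(0, 0.55), width = 0.35),
                          list(freqHz = 25, ampUv = 5,
                               center = c(0.35, -0.25), width = 0.35)),
                        noiseExponent = 1, noiseRmsUv = 10,
                        lineFreq = 50, lineAmpUv = 0, seed = 1L) {
  new("SynthConfig",
      nChannels = as.integer(nChannels), fs = as.numeric(fs),
      nCycles = as.integer(nCycles), cycleMeanS = cycleMeanS,
      cycleSdS = cycleSdS,
      artifactChannels = as.integer(artifactChannels),
      artifactAmpUv = as.numeric(artifactAmpUv),
      artifactJitterMs = as.numeric(artifactJitterMs),
      neuralSources = neuralSources,
      noiseExponent = noiseExponent, noiseRmsUv = noiseRmsUv,
      lineFreq = lineFreq, lineAmpUv = lineAmpUv,
      seed = as.integer(seed))
}

#' Concentric-ring sensor layout on the unit disc
#'
#' Deterministic 2-D layout standing in for an (unpublished) high-density cap
#' geometry: one central sensor plus concentric rings whose point counts grow
#' with radius.
#'
#' @param n number of sensors.
#' @return n x 2 matrix of coordinates on the unit disc.
#' @examples
#' xy <- sensorLayout(64)
#' plot(xy, asp = 1)
#' @export
sensorLayout <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(matrix(0, 1L, 2L, dimnames = list(NULL, c("x", "y"))))
  nRings <- max(1L, round(sqrt(n - 1L)))
  w <- seq_len(nRings)
  counts <- diff(c(0L, round(cumsum(w) / sum(w) * (n - 1L))))
  pts <- matrix(0, n, 2L)
  i <- 2L
  for (k in seq_len(nRings)) {
    m <- counts[k]
    if (m < 1L) next
    ang <- 2 * pi * (seq_len(m) - 1L) / m + 0.5 * k  # stagger rings
    r <- k / nRings
    pts[i:(i + m - 1L), ] <- cbind(r * cos(ang), r * sin(ang))
    i <- i + m
  }
  colnames(pts) <- c("x", "y")
  pts
}

## spectrally shaped Gaussian noise: amplitude ~ f^(-exponent/2), zero DC.
## FFT length padded to a highly composite size (fast mixed-radix), then cut.
pinkNoise <- function(n, exponent, rmsTarget) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white / stats::sd(white) * rmsTarget)
  m <- stats::nextn(n)
  spec <- stats::fft(c(white, numeric(m - n)))
  f <- c(0, pmin(seq_len(m - 1L), m - seq_len(m - 1L)))  # symmetric bin index
  shape <- c(0, f[-1L]^(-exponent / 2))
  x <- Re(stats::fft(spec * shape, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x) * rmsTarget
}

## stereotyped heel-strike-locked waveform: Gaussian transients shortly after
## contact (~50 ms) and at mid-stance (~300 ms), peak amplitude ampUv.
## widths (40/80 ms) keep the artifact spectrum below ~8 Hz, as expected for
## mechanical head/cable motion rather than oscillatory neural activity
artifactWaveform <- function(durSamples, fs, ampUv) {
  t <- (seq_len(durSamples) - 1L) / fs
  w <- exp(-(t - 0.05)^2 / (2 * 0.04^2)) +
    0.6 * exp(-(t - 0.30)^2 / (2 * 0.08^2))
  w / max(w) * ampUv
}

## smooth random amplitude envelope (mean 1): sources wax and wane the way
## ongoing band-limited EEG rhythms do, with no repetition across cycles
waxingEnvelope <- function(n, fs, depth = 0.5, timescaleS = 0.5) {
  w <- max(2L, round(timescaleS * fs))
  z <- stats::filter(stats::rnorm(n + 2L * w), rep(1 / w, w), sides = 2L)
  z <- z[w + seq_len(n)]
  1 + depth * (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic walking-EEG recording with ground truth
#'
#' Simulates a multichannel EEG during steady treadmill walking.  Every
#' channel receives spectrally shaped (1/f) background noise and spatially
#' mixed oscillatory sources; the channels listed in
#' \code{config@artifactChannels} additionally receive a stereotyped
#' heel-strike-locked artifact waveform (two Gaussian transients per cycle at
#' ~50 and ~300 ms after contact, jittered per cycle).  A vertical
#' ground-reaction-force trace is synthesised whose first upward 15 N
#' crossing of each cycle lands on the ground-truth contact sample.
#'
#' @param config a [SynthConfig-class].
#' @return A list with elements \code{recording} ([EEGRecording-class]),
#'   \code{grf} ([ForceSeries-class]), \code{events} ([GaitEvents-class],
#'   ground-truth heel strikes) and \code{truth}, a list with
#'   \code{artifactChannels}, \code{eventTimes} (0-based samples),
#'   \code{artifactSignal} (the pure artifact time course added to each
#'   artifact channel, channels x samples) and \code{neuralMaps}
#'   (channels x sources mixing used for the oscillatory sources).
#' @examples
#' out <- generateWalkingEEG(synthConfig(nChannels = 8, nCycles = 10,
#'                                       artifactChannels = 1:2, seed = 1))
#' out$recording
#' @export
generateWalkingEEG <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  set.seed(config@seed)
  fs <- config@fs

  ## gait cycle durations (s), truncated well away from zero
  dur <- stats::rnorm(config@nCycles, config@cycleMeanS, config@cycleSdS)
  dur <- pmax(dur, 0.4 * config@cycleMeanS)
  onsets <- round(c(0, cumsum(dur[-length(dur)])) * fs) + round(0.5 * fs)
  nSamp <- as.integer(max(onsets) + round(dur[length(dur)] * fs) +
                        round(0.5 * fs))

  pos <- sensorLayout(config@nChannels)
  data <- matrix(0, config@nChannels, nSamp)
  for (ch in seq_len(config@nChannels))
    data[ch, ] <- pinkNoise(nSamp, config@noiseExponent, config@noiseRmsUv)

  ## oscillatory neural sources, spatially mixed with smooth disc maps
  tSec <- (seq_len(nSamp) - 1L) / fs
  nSrc <- length(config@neuralSources)
  maps <- matrix(0, config@nChannels, max(1L, nSrc))
  for (k in seq_along(config@neuralSources)) {
    src <- config@neuralSources[[k]]
    d2 <- (pos[, 1L] - src$center[1L])^2 + (pos[, 2L] - src$center[2L])^2
    maps[, k] <- exp(-d2 / (2 * src$width^2))
    phase <- stats::runif(1, 0, 2 * pi)
    env <- waxingEnvelope(nSamp, fs)
    wave <- src$ampUv * env * sin(2 * pi * src$freqHz * tSec + phase)
    data <- data + maps[, k, drop = FALSE] %*% rbind(wave)
  }

  if (config@lineAmpUv > 0)
    data <- data + matrix(config@lineAmpUv *
                            sin(2 * pi * config@lineFreq * tSec),
                          config@nChannels, nSamp, byrow = TRUE)

  ## heel-strike-locked artifact on the designated channels only
  artSig <- NULL
  if (length(config@artifactChannels) && config@artifactAmpUv > 0) {
    artSig <- matrix(0, length(config@artifactChannels), nSamp)
    gains <- stats::runif(length(config@artifactChannels), 0.8, 1.2)
    for (ci in seq_along(config@artifactChannels)) {
      for (k in seq_len(config@nCycles)) {
        jit <- round(stats::rnorm(1, 0, config@artifactJitterMs / 1000 * fs))
        start <- onsets[k] + jit
        len <- min(round(0.5 * fs), nSamp - start)
        if (len < 2L || start < 0L) next
        idx <- start + seq_len(len)   # onsets are 0-based
        artSig[ci, idx] <- artSig[ci, idx] +
          artifactWaveform(len, fs, config@artifactAmpUv * gains[ci])
      }
    }
    data[config@artifactChannels, ] <-
      data[config@artifactChannels, , drop = FALSE] + artSig
  }

  events <- GaitEvents(onsets, "RHS")
  grf <- generateGRF(onsets, fs, stanceFraction = 0.65,
                     nSamples = nSamp)
  rec <- EEGRecording(data, fs, condition = "walking")
  rec@positions <- pos
  list(recording = rec, grf = grf, events = events,
       truth = list(artifactChannels = config@artifactChannels,
                    eventTimes = onsets,
                    artifactSignal = artSig,
                    neuralMaps = maps))
}

#' Synthesise a vertical ground-reaction-force trace
#'
#' Builds a double-bump stance-phase force profile for each gait cycle.  The
#' profile jumps from 0 to 30 N at the contact sample, so the first upward
#' 15 N crossing of every cycle recovers the ground-truth contact time
#' exactly, and drops back to 0 at the end of stance (toe-off).
#'
#' @param eventTimes ground-truth contact times, 0-based samples, increasing.
#' @param fs sampling rate, Hz.
#' @param stanceFraction stance duration as a fraction of the cycle; 0 gives
#'   an all-zero trace.
#' @param nSamples total length of the output trace; defaults to one mean
#'   cycle beyond the last event.
#' @param peakNewtons peak force (roughly body weight), newtons.
#' @return A [ForceSeries-class].
#' @examples
#' grf <- generateGRF(c(0, 512, 1024), fs = 512)
#' detectGaitEvents(grf)
#' @export
generateGRF <- function(eventTimes, fs, stanceFraction = 0.65,
                        nSamples = NULL, peakNewtons = 700) {
  eventTimes <- as.numeric(eventTimes)
  if (length(eventTimes) > 1L && any(diff(eventTimes) <= 0))
    stop("eventTimes must be strictly increasing")
  stopifnot(stanceFraction >= 0, stanceFraction < 1)
  gaps <- diff(eventTimes)
  medGap <- if (length(gaps)) stats::median(gaps) else round(1.2 * fs)
  if (is.null(nSamples))
    nSamples <- as.integer(max(eventTimes) + medGap + 1)
  force <- numeric(nSamples)
  if (stanceFraction == 0)
    return(ForceSeries(force, fs))
  L <- round(stanceFraction * medGap)     # stance scales with the median cycle
  for (k in seq_along(eventTimes)) {
    if (k < length(eventTimes) && eventTimes[k] + L >= eventTimes[k + 1L])
      stop("overlapping stance phases: reduce stanceFraction")
    if (L < 2L) next
    u <- (seq_len(L) - 1L) / (L - 1L)
    bump <- 0.85 * exp(-(u - 0.22)^2 / (2 * 0.12^2)) +
      0.80 * exp(-(u - 0.78)^2 / (2 * 0.12^2)) +
      0.45 * exp(-(u - 0.50)^2 / (2 * 0.22^2))
    prof <- 30 + (peakNewtons - 30) * bump / max(bump)
    prof[L] <- 20  # still above threshold; drops to 0 after stance
    idx <- eventTimes[k] + seq_len(L)  # 0-based event -> 1-based index
    keep <- idx <= nSamples
    force[idx[keep]] <- prof[keep]
  }
  ForceSeries(force, fs)
}
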