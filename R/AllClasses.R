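#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Multichannel EEG recording
#'
#' Container for a channels x samples EEG matrix in microvolts, together with
#' its sampling rate, channel labels, optional 2-D/3-D sensor positions and a
#' free-form condition tag (for instance \code{"eyes-open"} or
#' \code{"blindfolded"}).
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot labels character vector of unique channel labels (one per row).
#' @slot positions optional numeric matrix of sensor coordinates with one row
#'   per channel (2 or 3 columns), or \code{NULL}.
#' @slot condition single string tagging the recording condition.
#'
#' @seealso [EEGRecording()] for construction, [eegData()], [samplingRate()],
#'   [channelLabels()], [sensorPositions()], [recordingCondition()].
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    labels = "character",
    positions = "matrixOrNULL",
    condition = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@labels) != nrow(object@data))
    msg <- c(msg, "one label per channel required")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (!is.null(object@positions)) {
    if (nrow(object@positions) != nrow(object@data))
      msg <- c(msg, "positions must have one row per channel")
    if (!ncol(object@positions) %in% c(2L, 3L))
      msg <- c(msg, "positions must have 2 or 3 columns")
  }
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param labels channel labels; defaults to \code{"E1"}, \code{"E2"}, ...
#' @param positions optional per-channel sensor coordinates (2 or 3 columns).
#' @param condition condition tag, e.g. \code{"eyes-open"}.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512 * 4), nrow = 4), fs = 256)
#' nChannels(rec)
#' @export
EEGRecording <- function(data, fs, labels = NULL, positions = NULL,
                         condition = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels)) labels <- paste0("E", seq_len(nrow(data)))
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    storage.mode(positions) <- "double"
  }
  new("EEGRecording", data = data, fs = as.numeric(fs),
      labels = as.character(labels), positions = positions,
      condition = as.character(condition))
}

#' Gait (or surrogate) event series
#'
#' Ordered event times as 0-based sample indices with per-event labels.
#' Canonical labels are \code{RHS}/\code{LHS} (right/left heel strike),
#' \code{RTO}/\code{LTO} (toe-off) and \code{SURR} for surrogate events, but
#' any label is accepted.  The 0-based convention matches the on-disk
#' tab-separated event format (see [readEvents()]).
#'
#' @slot times numeric vector of strictly increasing 0-based sample indices.
#' @slot labels character vector, one label per event.
#' @export
setClass("GaitEvents",
  representation(times = "numeric", labels = "character")
)

setValidity("GaitEvents", function(object) {
  msg <- character()
  if (length(object@times) != length(object@labels))
    msg <- c(msg, "times and labels must have equal length")
  if (length(object@times) && any(!is.finite(object@times)))
    msg <- c(msg, "event times must be finite")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "event times must be strictly increasing")
  if (length(object@times) && any(object@times < 0))
    msg <- c(msg, "event times must be >= 0 (0-based samples)")
  if (length(msg)) msg else TRUE
})

#' Construct a GaitEvents series
#'
#' @param times strictly increasing 0-based sample indices.
#' @param labels per-event labels; recycled if a single string.
#' @return A [GaitEvents-class] object.
#' @export
GaitEvents <- function(times, labels = "RHS") {
  times <- as.numeric(times)
  if (length(labels) == 1L) labels <- rep(labels, length(times))
  new("GaitEvents", times = times, labels = as.character(labels))
}

#' Vertical ground-reaction-force series
#'
#' @slot samples force trace in newtons.
#' @slot fs sampling rate, Hz.
#' @export
setClass("ForceSeries",
  representation(samples = "numeric", fs = "numeric")
)

setValidity("ForceSeries", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a ForceSeries
#' @param samples force values, newtons.
#' @param fs sampling rate, Hz.
#' @return A [ForceSeries-class] object.
#' @export
ForceSeries <- function(samples, fs) {
  new("ForceSeries", samples = as.numeric(samples), fs = as.numeric(fs))
}

#' Set of time-warped gait-cycle epochs
#'
#' Each complete gait cycle (heel strike to next heel strike, or a fixed
#' window after a surrogate event) is linearly resampled to a common length of
#' \code{warpPoints} points, per channel.  The array is epochs x points x
#' channels; \code{durations} records the original (unwarped) epoch lengths in
#' samples of the series that was epoched.
#'
#' @slot epochs numeric array, epochs x warpPoints x channels.
#' @slot durations original epoch lengths (samples), one per epoch.
#' @slot channelLabels channel labels for the third dimension.
#' @export
setClass("EpochSet",
  representation(
    epochs = "array",
    durations = "numeric",
    channelLabels = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-D array")
  else {
    if (length(object@durations) != d[1L])
      msg <- c(msg, "one duration per epoch required")
    if (length(object@channelLabels) != d[3L])
      msg <- c(msg, "one label per channel required")
  }
  if (length(msg)) msg else TRUE
})

#' Tunable parameters of the template-correlation screen
#'
#' Defaults follow the published calibration of the method: epochs counted as
#' template-correlated at Pearson r > 0.4, channels flagged when more than 75
#' percent of their epochs correlate, 100 ms moving-average smoothing stepped
#' every 50 ms, warping to 1,000 points, amplitude range over 10 percent
#' windows, and a surrogate null of 10 random-event sets drawn in 5 equal
#' recording sectors at half the experimental cycle count.
#'
#' @slot corrThreshold Pearson r above which an epoch counts as correlated.
#' @slot fractionThreshold fraction of epochs above which a channel/component
#'   is a rejection candidate.
#' @slot smoothWindowMs moving-average window, ms.
#' @slot smoothStepMs moving-average step, ms.
#' @slot warpPoints common warped epoch length, points.
#' @slot rangeWindowFraction window size for the amplitude range, fraction of
#'   the warped epoch.
#' @slot nSurrogateSets number of surrogate event sets.
#' @slot surrogateSectors number of equal-duration recording sectors.
#' @slot surrogateFraction surrogate events per set as a fraction of the
#'   experimental cycle count.
#' @export
setClass("TcrParams",
  representation(
    corrThreshold = "numeric",
    fractionThreshold = "numeric",
    smoothWindowMs = "numeric",
    smoothStepMs = "numeric",
    warpPoints = "integer",
    rangeWindowFraction = "numeric",
    nSurrogateSets = "integer",
    surrogateSectors = "integer",
    surrogateFraction = "numeric"
  )
)

setValidity("TcrParams", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
  if (!inUnit(object@corrThreshold))
    msg <- c(msg, "corrThreshold must be in (0, 1)")
  if (!inUnit(object@fractionThreshold))
    msg <- c(msg, "fractionThreshold must be in (0, 1)")
  if (object@warpPoints < 100L)
    msg <- c(msg, "warpPoints must be >= 100")
  if (object@smoothWindowMs < object@smoothStepMs)
    msg <- c(msg, "smoothing window must be >= step")
  if (!inUnit(object@rangeWindowFraction))
    msg <- c(msg, "rangeWindowFraction must be in (0, 1)")
  if (object@nSurrogateSets < 1L || object@surrogateSectors < 1L)
    msg <- c(msg, "surrogate set and sector counts must be >= 1")
  if (!inUnit(object@surrogateFraction))
    msg <- c(msg, "surrogateFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct TcrParams
#'
#' @param corrThreshold,fractionThreshold,smoothWindowMs,smoothStepMs
#'   see [TcrParams-class].
#' @param warpPoints,rangeWindowFraction,nSurrogateSets,surrogateSectors
#'   see [TcrParams-class].
#' @param surrogateFraction see [TcrParams-class].
#' @return A [TcrParams-class] object.
#' @examples
#' tcrParams(corrThreshold = 0.5)
#' @export
tcrParams <- function(corrThreshold = 0.4, fractionThreshold = 0.75,
                      smoothWindowMs = 100, smoothStepMs = 50,
                      warpPoints = 1000L, rangeWindowFraction = 0.1,
                      nSurrogateSets = 10L, surrogateSectors = 5L,
                      surrogateFraction = 0.5) {
  new("TcrParams",
      corrThreshold = corrThreshold,
      fractionThreshold = fractionThreshold,
      smoothWindowMs = smoothWindowMs,
      smoothStepMs = smoothStepMs,
      warpPoints = as.integer(warpPoints),
      rangeWindowFraction = rangeWindowFraction,
      nSurrogateSets = as.integer(nSurrogateSets),
      surrogateSectors = as.integer(surrogateSectors),
      surrogateFraction = surrogateFraction)
}

#' Per-channel template-correlation statistics for one condition
#'
#' Result of [tcrChannelStats()]: the epoch x channel correlation table, the
#' per-channel fraction of epochs correlated above the threshold, the
#' per-channel amplitude range (ARNG) of the smoothed warped epochs, and the
#' knee ("breaking point") of the ascending sorted ARNG curve.
#'
#' @slot condition condition tag carried over from the recording.
#' @slot corr epochs x channels matrix of Pearson correlations.
#' @slot fraction named per-channel fraction of epochs with r above threshold.
#' @slot arng named per-channel amplitude range, microvolts.
#' @slot breakingIndex index into the ascending sorted ARNG curve where the
#'   steady rise begins (NA when the curve has no knee).
#' @slot breakingValue ARNG value at the breaking point (microvolts; NA when
#'   no knee).
#' @slot params the [TcrParams-class] used.
#' @export
setClass("TcrChannelStats",
  representation(
    condition = "character",
    corr = "matrix",
    fraction = "numeric",
    arng = "numeric",
    breakingIndex = "integer",
    breakingValue = "numeric",
    params = "TcrParams"
  )
)

#' Channel rejection decision record
#'
#' Per-channel flags with machine-readable evidence.  Reason codes:
#' \code{LOW_RANGE}, \code{HIGH_RANGE}, \code{KURTOSIS}, \code{NEIGHBOR_CORR},
#' \code{STD_OUTLIER} (conventional "method 1" screening) and \code{TCR}
#' (template-correlation rejection).
#'
#' @slot labels channel labels.
#' @slot flagged logical per-channel rejection flag.
#' @slot reasons list of character vectors of reason codes, one per channel.
#' @slot evidence data.frame of the numeric evidence behind each decision.
#' @slot method short description of the deciding procedure.
#' @export
setClass("ChannelDecision",
  representation(
    labels = "character",
    flagged = "logical",
    reasons = "list",
    evidence = "data.frame",
    method = "character"
  )
)

setValidity("ChannelDecision", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (length(object@flagged) != n || length(object@reasons) != n)
    msg <- c(msg, "flagged and reasons must match labels in length")
  bad <- which(object@flagged & !vapply(object@reasons, length, 1L))
  if (length(bad))
    msg <- c(msg, "every flagged channel needs at least one reason code")
  if (length(msg)) msg else TRUE
})

#' Independent-component decomposition
#'
#' A linear decomposition of an EEG recording: component activations (rows),
#' the mixing matrix whose columns are scalp maps, and optionally the
#' unmixing matrix.  When both matrices are present, mixing %*% unmixing must
#' act as the identity on the retained channel subspace.
#'
#' @slot activations components x samples matrix (arbitrary units).
#' @slot mixing channels x components matrix (scalp maps as columns).
#' @slot unmixing components x channels matrix, or NULL.
#' @slot fs sampling rate of the activations, Hz.
#' @export
setClass("ICSet",
  representation(
    activations = "matrix",
    mixing = "matrix",
    unmixing = "matrixOrNULL",
    fs = "numeric"
  )
)

setValidity("ICSet", function(object) {
  msg <- character()
  k <- nrow(object@activations)
  if (ncol(object@mixing) != k)
    msg <- c(msg, "mixing must have one column per component")
  if (k > nrow(object@mixing))
    msg <- c(msg, "component count must not exceed channel count")
  if (!is.null(object@unmixing)) {
    if (!all(dim(object@unmixing) == rev(dim(object@mixing))))
      msg <- c(msg, "unmixing must be the transpose shape of mixing")
    else {
      p <- object@unmixing %*% object@mixing   # components x components
      if (max(abs(p - diag(nrow(p)))) > 1e-6)
        msg <- c(msg, "unmixing %*% mixing must be the identity")
    }
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an ICSet
#'
#' @param activations components x samples matrix; if NULL, computed as
#'   \code{unmixing \%*\% data} is the caller's job - activations are required
#'   here.
#' @param mixing channels x components matrix.
#' @param unmixing optional components x channels matrix.
#' @param fs sampling rate, Hz.
#' @return An [ICSet-class] object.
#' @export
ICSet <- function(activations, mixing, unmixing = NULL, fs) {
  activations <- as.matrix(activations)
  mixing <- as.matrix(mixing)
  if (!is.null(unmixing)) unmixing <- as.matrix(unmixing)
  new("ICSet", activations = activations, mixing = mixing,
      unmixing = unmixing, fs = as.numeric(fs))
}

#' Independent-component rejection decision record
#'
#' @slot flagged logical per-component rejection flag.
#' @slot evidence data.frame with per-component TCR fraction, spectral-peak
#'   record (band, frequency, prominence), scalp-map smoothness and the
#'   resulting neural-evidence verdict.
#' @slot override integer indices of components whose automatic decision was
#'   manually overridden (kept for audit).
#' @export
setClass("ICDecision",
  representation(
    flagged = "logical",
    evidence = "data.frame",
    override = "integer"
  )
)

#' Event-locked amplitude map for one channel
#'
#' Epochs x time matrix of RMS-smoothed amplitude aligned to gait events,
#' with the event-relative time axis and the across-epoch mean trace.
#'
#' @slot map epochs x time numeric matrix, RMS microvolts.
#' @slot time event-relative time axis, seconds.
#' @slot meanTrace across-epoch mean of \code{map}.
#' @slot channel channel label.
#' @export
setClass("GaitAmplitudeMap",
  representation(
    map = "matrix",
    time = "numeric",
    meanTrace = "numeric",
    channel = "character"
  )
)

#' Configuration of the synthetic walking-EEG generator
#'
#' See [generateWalkingEEG()] for the generative model.  Defaults emulate a
#' high-density (256-channel) treadmill-walking recording: 512 Hz sampling,
#' gait cycles of 1.2 +/- 0.1 s, pink (1/f) background noise, two oscillatory
#' neural sources at 10 and 25 Hz with smooth scalp topographies, and a
#' stereotyped heel-strike-locked artifact waveform added on a subset of
#' channels.
#'
#' @slot nChannels number of channels.
#' @slot fs sampling rate, Hz.
#' @slot nCycles number of gait cycles.
#' @slot cycleMeanS mean gait-cycle duration, seconds.
#' @slot cycleSdS SD of cycle duration, seconds.
#' @slot artifactChannels 1-based indices of channels receiving the artifact.
#' @slot artifactAmpUv artifact peak amplitude, microvolts.
#' @slot artifactJitterMs SD of per-cycle artifact timing jitter, ms.
#' @slot neuralSources list of sources, each
#'   \code{list(freqHz=, ampUv=, center=c(x, y), width=)}.
#' @slot noiseExponent spectral slope of the 1/f background.
#' @slot noiseRmsUv RMS of the background noise, microvolts.
#' @slot lineFreq mains frequency, Hz.
#' @slot lineAmpUv mains amplitude, microvolts (0 disables).
#' @slot seed integer RNG seed.
#' @export
setClass("SynthConfig",
  representation(
    nChannels = "integer",
    fs = "numeric",
    nCycles = "integer",
    cycleMeanS = "numeric",
    cycleSdS = "numeric",
    artifactChannels = "integer",
    artifactAmpUv = "numeric",
    artifactJitterMs = "numeric",
    neuralSources = "list",
    noiseExponent = "numeric",
    noiseRmsUv = "numeric",
    lineFreq = "numeric",
    lineAmpUv = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nCycles < 10L) msg <- c(msg, "nCycles must be >= 10")
  if (object@cycleMeanS <= 0) msg <- c(msg, "cycleMeanS must be > 0")
  if (length(object@artifactChannels) &&
      (min(object@artifactChannels) < 1L ||
       max(object@artifactChannels) > object@nChannels))
    msg <- c(msg, "artifactChannels out of range")
  fmax <- max(c(0, vapply(object@neuralSources,
                          function(s) s$freqHz, numeric(1))))
  if (object@fs <= 2 * fmax)
    msg <- c(msg, "fs must exceed twice the highest source frequency")
  if (object@cycleSdS < 0) msg <- c(msg, "cycleSdS must be >= 0")
  if (length(msg)) msg else TRUE
})
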