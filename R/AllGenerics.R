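#' @include AllClasses.R
NULL

#' Accessors for gaitTCR objects
#'
#' Standard read accessors: \code{eegData} returns the channels x samples
#' matrix, \code{samplingRate} the rate in Hz, \code{channelLabels} the
#' per-channel labels, \code{sensorPositions} the coordinate matrix (or
#' \code{NULL}), \code{recordingCondition} the condition tag,
#' \code{nChannels}/\code{nSamples} the matrix dimensions, \code{eventTimes}
#' and \code{eventLabels} the event series contents, \code{forceSamples} the
#' force trace, \code{epochArray} the epochs x points x channels array,
#' \code{nEpochs}/\code{warpPoints} its dimensions, \code{flaggedIndices}
#' the indices flagged by a decision and \code{decisionEvidence} its evidence
#' table.
#'
#' @param x a gaitTCR object.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases eegData samplingRate channelLabels sensorPositions
#'   recordingCondition nChannels nSamples eventTimes eventLabels
#'   forceSamples epochArray nEpochs warpPoints flaggedIndices
#'   decisionEvidence
#' @examples
#' rec <- EEGRecording(matrix(0, 2, 100), fs = 100)
#' samplingRate(rec)
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))
#' @rdname accessors
#' @export
setGeneric("recordingCondition",
           function(x) standardGeneric("recordingCondition"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))
#' @rdname accessors
#' @export
setGeneric("forceSamples", function(x) standardGeneric("forceSamples"))
#' @rdname accessors
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("warpPoints", function(x) standardGeneric("warpPoints"))
#' @rdname accessors
#' @export
setGeneric("flaggedIndices", function(x) standardGeneric("flaggedIndices"))
#' @rdname accessors
#' @export
setGeneric("decisionEvidence",
           function(x) standardGeneric("decisionEvidence"))

setMethod("eegData", "EEGRecording", function(x) x@data)
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
setMethod("samplingRate", "ForceSeries", function(x) x@fs)
setMethod("samplingRate", "ICSet", function(x) x@fs)
setMethod("channelLabels", "EEGRecording", function(x) x@labels)
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
setMethod("sensorPositions", "EEGRecording", function(x) x@positions)
setMethod("recordingCondition", "EEGRecording", function(x) x@condition)
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
setMethod("nChannels", "EpochSet", function(x) dim(x@epochs)[3L])
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))
setMethod("eventTimes", "GaitEvents", function(x) x@times)
setMethod("eventLabels", "GaitEvents", function(x) x@labels)
setMethod("forceSamples", "ForceSeries", function(x) x@samples)
setMethod("epochArray", "EpochSet", function(x) x@epochs)
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1L])
setMethod("warpPoints", "EpochSet", function(x) dim(x@epochs)[2L])
setMethod("warpPoints", "TcrParams", function(x) x@warpPoints)
setMethod("flaggedIndices", "ChannelDecision", function(x) which(x@flagged))
setMethod("flaggedIndices", "ICDecision", function(x) which(x@flagged))
setMethod("decisionEvidence", "ChannelDecision", function(x) x@evidence)
setMethod("decisionEvidence", "ICDecision", function(x) x@evidence)

setMethod("length", "GaitEvents", function(x) length(x@times))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs,
    if (nzchar(object@condition))
      sprintf(", condition '%s'", object@condition) else ""))
  if (!is.null(object@positions))
    cat(sprintf("  sensor positions: %d-D\n", ncol(object@positions)))
})

setMethod("show", "GaitEvents", function(object) {
  cat(sprintf("GaitEvents: %d events (%s)\n", length(object@times),
              paste(utils::head(unique(object@labels), 6), collapse = ", ")))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs x %d warped points x %d channels\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  original epoch length: %.0f-%.0f samples (median %.0f)\n",
              min(object@durations), max(object@durations),
              stats::median(object@durations)))
})

setMethod("show", "TcrChannelStats", function(object) {
  cat(sprintf(
    "TcrChannelStats (%s): %d epochs x %d channels\n",
    if (nzchar(object@condition)) object@condition else "unnamed condition",
    nrow(object@corr), ncol(object@corr)))
  cat(sprintf("  epochs correlated at r > %.2f: median fraction %.2f (max %.2f)\n",
              object@params@corrThreshold,
              stats::median(object@fraction), max(object@fraction)))
  if (is.na(object@breakingIndex))
    cat("  amplitude breaking point: none (flat sorted ARNG curve)\n")
  else
    cat(sprintf("  amplitude breaking point: %.2f uV (sorted index %d/%d)\n",
                object@breakingValue, object@breakingIndex,
                length(object@arng)))
})

setMethod("show", "ChannelDecision", function(object) {
  n <- sum(object@flagged)
  cat(sprintf("ChannelDecision [%s]: %d of %d channels flagged\n",
              object@method, n, length(object@flagged)))
  if (n) {
    codes <- sort(table(unlist(object@reasons)), decreasing = TRUE)
    cat("  reasons:",
        paste(sprintf("%s x%d", names(codes), codes), collapse = ", "), "\n")
  }
})

setMethod("show", "ICSet", function(object) {
  cat(sprintf("ICSet: %d components over %d channels, %d samples @ %g Hz\n",
              nrow(object@activations), nrow(object@mixing),
              ncol(object@activations), object@fs))
})

setMethod("show", "ICDecision", function(object) {
  cat(sprintf("ICDecision: %d of %d components flagged for rejection\n",
              sum(object@flagged), length(object@flagged)))
  kept <- which(!object@flagged & object@evidence$fraction >
                  object@evidence$fractionThreshold)
  if (length(kept))
    cat("  retained despite high template fraction (neural evidence):",
        paste(kept, collapse = ", "), "\n")
})

setMethod("show", "GaitAmplitudeMap", function(object) {
  cat(sprintf(
    "GaitAmplitudeMap [%s]: %d epochs, %.2f to %.2f s around the event\n",
    object@channel, nrow(object@map), min(object@time), max(object@time)))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %d channels @ %g Hz, %d cycles of %.2f +/- %.2f s\n",
    object@nChannels, object@fs, object@nCycles, object@cycleMeanS,
    object@cycleSdS))
  cat(sprintf("  artifact: %d channels at %.0f uV (jitter %.0f ms); seed %d\n",
              length(object@artifactChannels), object@artifactAmpUv,
              object@artifactJitterMs, object@seed))
})
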