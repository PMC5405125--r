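#' @include AllClasses.R
NULL

#' Moving-average smoothing on a decimated grid
#'
#' Averages the signal in windows of \code{windowMs} stepped every
#' \code{stepMs} (50 percent overlap at the defaults), emitting one value per
#' step.  Output value k is the mean of the samples in the window starting at
#' sample k * step (0-based), so the output length is
#' \code{floor((n - window) / step) + 1}.  The step and window sizes (in
#' original samples) are attached as attributes \code{"step"},
#' \code{"window"} and \code{"fs"} so that downstream epoching can convert
#' event times.
#'
#' @param x numeric vector, channels x samples matrix, or
#'   [EEGRecording-class].
#' @param fs sampling rate, Hz (taken from the recording when given one).
#' @param windowMs window length, ms.
#' @param stepMs step between window starts, ms.
#' @return Smoothed vector (or channels x steps matrix) with attributes
#'   \code{step}, \code{window}, \code{fs}.
#' @examples
#' smoothMovingAverage(rep(2, 1000), fs = 512)[1:5]
#' @export
smoothMovingAverage <- function(x, fs = NULL, windowMs = 100, stepMs = 50) {
  if (is(x, "EEGRecording")) {
    fs <- x@fs
    x <- x@data
  }
  if (is.null(fs)) stop("fs required")
  win <- max(1L, round(windowMs / 1000 * fs))
  step <- max(1L, round(stepMs / 1000 * fs))
  if (win < step) stop("window must be >= step")
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n < win) stop("signal shorter than one smoothing window")
  nOut <- (n - win) %/% step + 1L
  starts <- (seq_len(nOut) - 1L) * step
  one <- function(v) {
    cs <- cumsum(v)
    (cs[starts + win] - c(0, cs)[starts + 1L]) / win
  }
  out <- if (is.matrix(x)) t(apply(x, 1L, one)) else one(as.numeric(x))
  attr(out, "step") <- step
  attr(out, "window") <- win
  attr(out, "fs") <- fs
  out
}

## linearly resample one segment to m points, endpoints preserved
warpSegment <- function(y, m) {
  n <- length(y)
  if (n == m) return(y)
  stats::approx(seq(0, 1, length.out = n), y,
                seq(0, 1, length.out = m))$y
}

#' Cut a series into gait-cycle epochs and time-warp them
#'
#' Segments the (typically smoothed) series at the event times - heel strike
#' to next heel strike - and linearly resamples every segment to exactly
#' \code{warpPoints} points, preserving the first and last point of each
#' segment.  When \code{epochLenSamples} is given, fixed-length windows
#' starting at each event are used instead (the surrogate-epoch mode);
#' windows that would run past the end of the series are dropped.
#'
#' @param x numeric vector or channels x steps matrix, usually the output of
#'   [smoothMovingAverage()] (its \code{step} attribute converts event times
#'   from original samples to smoothed steps; raw series have step 1).
#' @param events [GaitEvents-class] or numeric 0-based sample times at the
#'   original sampling rate.
#' @param warpPoints common warped length.
#' @param step samples per series point; defaults to the \code{step}
#'   attribute of \code{x}, else 1.
#' @param epochLenSamples optional fixed epoch length in original samples.
#' @return An [EpochSet-class].
#' @examples
#' ev <- c(0, 500)
#' es <- epochAndWarp(seq(0, 1, length.out = 600), ev, warpPoints = 1000)
#' dim(epochArray(es))
#' @export
epochAndWarp <- function(x, events, warpPoints = 1000L, step = NULL,
                         epochLenSamples = NULL) {
  if (is(events, "GaitEvents")) events <- events@times
  events <- as.numeric(events)
  if (is.null(step)) step <- attr(x, "step")
  if (is.null(step)) step <- 1L
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  nPts <- ncol(x)
  warpPoints <- as.integer(warpPoints)
  evIdx <- floor(events / step) + 1L           # 0-based samples -> 1-based
  evIdx <- evIdx[evIdx >= 1L & evIdx <= nPts + 1L]  # end may sit one past
  if (is.null(epochLenSamples)) {
    if (length(evIdx) < 2L) stop("need at least 2 events to form epochs")
    starts <- evIdx[-length(evIdx)]
    ends <- evIdx[-1L]                          # half-open [start, end)
  } else {
    len <- max(2L, round(epochLenSamples / step))
    starts <- evIdx
    ends <- evIdx + len
    drop <- ends > nPts + 1L | starts > nPts
    if (any(drop)) {
      starts <- starts[!drop]
      ends <- ends[!drop]
    }
    if (!length(starts)) stop("no surrogate epoch fits within the series")
  }
  lens <- ends - starts
  bad <- lens < 2L
  if (any(bad)) {
    warning(sum(bad), " degenerate (near zero-length) cycle(s) skipped")
    starts <- starts[!bad]; ends <- ends[!bad]; lens <- lens[!bad]
  }
  nEp <- length(starts)
  if (!nEp) stop("no usable epochs")
  arr <- array(NA_real_, c(nEp, warpPoints, nrow(x)))
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    for (i in seq_len(nEp))
      arr[i, , ch] <- warpSegment(v[starts[i]:(ends[i] - 1L)], warpPoints)
  }
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("E", seq_len(nrow(x)))
  new("EpochSet", epochs = arr, durations = as.numeric(lens) * step,
      channelLabels = labs)
}

#' Across-epoch average template
#'
#' The pointwise arithmetic mean of all time-warped epochs, per channel: the
#' waveform against which every individual gait cycle is correlated.
#'
#' @param epochs an [EpochSet-class], or an epochs x points matrix for a
#'   single channel.
#' @return warpPoints x channels matrix (or a vector for matrix input).
#' @export
computeTemplate <- function(epochs) {
  if (is(epochs, "EpochSet")) {
    tmpl <- apply(epochs@epochs, c(2L, 3L), mean)
    colnames(tmpl) <- epochs@channelLabels
    return(tmpl)
  }
  colMeans(as.matrix(epochs))
}

#' Pearson correlation of each epoch with the template
#'
#' Standard Pearson coefficient between every warped epoch and the
#' per-channel template.  Epochs or templates with zero variance get the
#' sentinel value 0 (counting as below any positive threshold), so the
#' fraction statistic stays total.
#'
#' @param epochs an [EpochSet-class] or epochs x points matrix.
#' @param template output of [computeTemplate()]; recomputed when missing.
#' @return epochs x channels matrix of correlations in [-1, 1] (a vector for
#'   single-channel matrix input).
#' @export
epochTemplateCorrelations <- function(epochs, template = NULL) {
  one <- function(E, tm) {
    if (length(tm) != ncol(E)) stop("template/epoch length mismatch")
    r <- suppressWarnings(as.vector(stats::cor(t(E), tm)))
    r[!is.finite(r)] <- 0
    r
  }
  if (is(epochs, "EpochSet")) {
    if (is.null(template)) template <- computeTemplate(epochs)
    template <- as.matrix(template)
    nc <- dim(epochs@epochs)[3L]
    out <- matrix(0, dim(epochs@epochs)[1L], nc)
    for (ch in seq_len(nc))
      out[, ch] <- one(epochs@epochs[, , ch, drop = TRUE], template[, ch])
    colnames(out) <- epochs@channelLabels
    return(out)
  }
  E <- as.matrix(epochs)
  if (is.null(template)) template <- colMeans(E)
  one(E, as.numeric(template))
}

#' Fraction of epochs correlated above threshold
#'
#' Per channel, the proportion of epochs whose template correlation exceeds
#' the threshold.  The comparison is signed: anticorrelated epochs do not
#' count.
#'
#' @param corr epochs x channels correlation matrix (or a vector).
#' @param threshold Pearson r threshold.
#' @return Named per-channel fractions in [0, 1].
#' @examples
#' fractionCorrelated(c(0.5, 0.3, 0.45, 0.41), 0.4)  # 0.75
#' @export
fractionCorrelated <- function(corr, threshold = 0.4) {
  if (is.matrix(corr)) colMeans(corr > threshold) else mean(corr > threshold)
}

#' Per-channel amplitude range (ARNG) of warped epochs
#'
#' Each warped epoch is split into \code{1 / windowFraction} equal windows;
#' the range (max - min) is taken per window and averaged over windows, then
#' over epochs.  Windowing makes the statistic robust to isolated short
#' spikes: a single-sample spike inflates only one of the ten windows.
#'
#' @param epochs an [EpochSet-class] or epochs x points matrix.
#' @param windowFraction window size as a fraction of the epoch; the warped
#'   length must be divisible by the window count.
#' @return Named per-channel ARNG in microvolts (scalar for matrix input).
#' @export
amplitudeRange <- function(epochs, windowFraction = 0.1) {
  one <- function(E) {
    p <- ncol(E)
    nWin <- round(1 / windowFraction)
    if (p %% nWin != 0L)
      stop("warped length ", p, " not divisible into ", nWin, " windows")
    wlen <- p %/% nWin
    a <- array(t(E), c(wlen, nWin, nrow(E)))
    rngs <- apply(a, c(2L, 3L), function(v) max(v) - min(v))
    mean(colMeans(rngs))
  }
  if (is(epochs, "EpochSet")) {
    nc <- dim(epochs@epochs)[3L]
    out <- vapply(seq_len(nc),
                  function(ch) one(epochs@epochs[, , ch, drop = TRUE]),
                  numeric(1))
    names(out) <- epochs@channelLabels
    return(out)
  }
  one(as.matrix(epochs))
}

#' Knee ("breaking point") of an ascending sorted curve
#'
#' Finds the point where a sorted amplitude curve starts to rise steadily:
#' the point with maximum perpendicular distance to the chord joining the
#' first and last points, after normalising both axes to [0, 1] (which makes
#' the result invariant to amplitude rescaling).  Ties break toward the
#' smaller index; a curve that is straight within tolerance has no knee and
#' returns NA.
#'
#' @param values numeric vector (sorted ascending; sorted internally
#'   otherwise).
#' @param tol relative straightness tolerance.
#' @return List with \code{index} (into the sorted curve), \code{value}, and
#'   \code{distance} (the maximal normalised chord distance); \code{index}
#'   and \code{value} are NA when the curve has no knee.
#' @examples
#' findBreakingPoint(c(rep(5, 10), 10, 20, 30, 40, 50))
#' @export
findBreakingPoint <- function(values, tol = 1e-9) {
  v <- as.numeric(values)
  if (length(v) < 5L) stop("need at least 5 values")
  if (is.unsorted(v)) v <- sort(v)
  n <- length(v)
  if (any(v < 0)) stop("amplitude values must be non-negative")
  span <- v[n] - v[1L]
  if (span <= tol * max(abs(v), 1))
    return(list(index = NA_integer_, value = NA_real_, distance = 0))
  x <- (seq_len(n) - 1L) / (n - 1L)
  y <- (v - v[1L]) / span
  d <- abs(x - y) / sqrt(2)       # perpendicular distance to the unit chord
  if (max(d) < tol)
    return(list(index = NA_integer_, value = NA_real_, distance = max(d)))
  i <- which.max(d)               # first max: ties toward the smaller index
  list(index = as.integer(i), value = v[i], distance = d[i])
}

#' Ensemble of surrogate (random) event sets
#'
#' @slot sets list of [GaitEvents-class], one per surrogate set.
#' @slot seed integer seed used.
#' @slot sectors number of equal-duration sectors.
#' @slot fraction surrogate events per set as a fraction of the cycle count.
#' @slot epochLenSamples fixed surrogate epoch length, original samples.
#' @export
setClass("SurrogateEnsemble",
  representation(sets = "list", seed = "integer", sectors = "integer",
                 fraction = "numeric", epochLenSamples = "numeric"))

setMethod("show", "SurrogateEnsemble", function(object) {
  cat(sprintf(
    "SurrogateEnsemble: %d sets of %d events in %d sectors (seed %d)\n",
    length(object@sets), length(object@sets[[1L]]@times), object@sectors,
    object@seed))
})

#' Generate surrogate (random-timing) event sets
#'
#' Builds the null model for the template-correlation statistic: several
#' sets of randomly timed pseudo-events, each containing
#' \code{round(fraction * nCycles)} events (half the cycle count by default,
#' to keep surrogate epochs from overlapping too often), stratified over
#' \code{sectors} equal-duration portions of the recording so the events
#' cover the whole session evenly.  Per-sector counts differ by at most one.
#'
#' @param recordingLen recording length, samples.
#' @param fs sampling rate, Hz.
#' @param nCycles number of experimental gait cycles.
#' @param nSets number of surrogate sets.
#' @param sectors number of equal recording sectors.
#' @param fraction events per set as a fraction of \code{nCycles}.
#' @param seed integer seed; the ensemble is reproducible.
#' @param epochLenSamples epoch length attached to each surrogate event;
#'   defaults to \code{recordingLen / nCycles} (the mean cycle).
#' @return A [SurrogateEnsemble-class].
#' @export
generateSurrogateEvents <- function(recordingLen, fs, nCycles, nSets = 10L,
                                    sectors = 5L, fraction = 0.5,
                                    seed = 1L, epochLenSamples = NULL) {
  recordingLen <- as.numeric(recordingLen)
  if (is.null(epochLenSamples)) epochLenSamples <- recordingLen / nCycles
  nEv <- round(fraction * nCycles)
  if (nEv < 1L) stop("fraction * nCycles must be at least 1")
  if (nEv * epochLenSamples > recordingLen)
    stop("infeasible density: expected total epoch length exceeds recording")
  sectorLen <- floor(recordingLen / sectors)
  counts <- rep(nEv %/% sectors, sectors)
  rem <- nEv %% sectors
  if (rem) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  set.seed(as.integer(seed))
  sets <- vector("list", nSets)
  for (s in seq_len(nSets)) {
    times <- unlist(lapply(seq_len(sectors), function(k) {
      sort(sample.int(sectorLen, counts[k])) + (k - 1L) * sectorLen - 1L
    }))
    sets[[s]] <- GaitEvents(times, "SURR")
  }
  new("SurrogateEnsemble", sets = sets, seed = as.integer(seed),
      sectors = as.integer(sectors), fraction = fraction,
      epochLenSamples = epochLenSamples)
}

#' Chance-level correlation threshold from distribution intersection
#'
#' Kernel-density estimates (Silverman bandwidth, boundary reflection onto
#' [-1, 1]) of the experimental and surrogate correlation samples are
#' compared; the threshold r* is the rightmost point where the rising
#' experimental density crosses above the falling surrogate density.  Above
#' r* the experimental correlations occur beyond chance level.  When the
#' two distributions are indistinguishable (no such crossing) the sentinel
#' \code{noSeparation = TRUE} is returned and callers fall back to
#' \code{defaultThreshold}.
#'
#' @param expCorrs experimental correlation sample (>= 100 values).
#' @param surrCorrs surrogate correlation sample (>= 100 values).
#' @param defaultThreshold fixed fallback threshold, reported alongside.
#' @param gridN density grid size on [-1, 1].
#' @return List with \code{rStar}, \code{noSeparation},
#'   \code{defaultThreshold}, and the density grids (\code{grid},
#'   \code{densExperimental}, \code{densSurrogate}) for plotting.
#' @export
estimateCorrelationThreshold <- function(expCorrs, surrCorrs,
                                         defaultThreshold = 0.4,
                                         gridN = 1024L) {
  expCorrs <- expCorrs[is.finite(expCorrs)]
  surrCorrs <- surrCorrs[is.finite(surrCorrs)]
  if (length(expCorrs) < 100L || length(surrCorrs) < 100L)
    stop("need at least 100 correlation values in each sample")
  kde <- function(x) {
    bw <- stats::bw.nrd0(x)
    d <- stats::density(c(x, -2 - x, 2 - x), bw = bw, from = -1, to = 1,
                        n = gridN)
    list(x = d$x, y = 3 * d$y)    # refold reflected mass
  }
  de <- kde(expCorrs)
  ds <- kde(surrCorrs)
  grid <- de$x
  out <- list(rStar = NA_real_, noSeparation = TRUE,
              defaultThreshold = defaultThreshold, grid = grid,
              densExperimental = de$y, densSurrogate = ds$y)
  diffd <- de$y - ds$y
  idx <- seq_len(gridN - 1L)
  ## up-crossings where the experimental density rises above the falling
  ## surrogate density (the experimental curve may itself be falling more
  ## slowly on a fat right shoulder; what matters is the surrogate flank)
  rising <- which(diffd[idx] <= 0 & diffd[idx + 1L] > 0 &
                    ds$y[idx + 1L] < ds$y[idx])
  if (!length(rising)) return(out)
  i <- max(rising)                # rightmost qualifying crossing
  ## linear interpolation of the zero crossing between grid points
  x0 <- grid[i]; x1 <- grid[i + 1L]
  y0 <- diffd[i]; y1 <- diffd[i + 1L]
  out$rStar <- if (y1 == y0) x0 else x0 - y0 * (x1 - x0) / (y1 - y0)
  out$noSeparation <- FALSE
  out
}

#' Per-channel TCR statistics for one condition
#'
#' Runs the full first stage of the template-correlation screen on a
#' recording: moving-average smoothing, heel-strike-to-heel-strike epoching
#' with time-warping to a common length, across-epoch template, per-epoch
#' Pearson correlations, fraction of epochs above the correlation threshold,
#' per-channel amplitude range of the warped epochs, and the breaking point
#' of the ascending sorted amplitude curve.  The smoothing and warping are
#' applied to a working copy only; the input recording is untouched.
#'
#' @param recording an [EEGRecording-class].
#' @param events [GaitEvents-class] of heel strikes of one foot (epochs run
#'   from each event to the next), or the ground-truth event times.
#' @param params a [TcrParams-class].
#' @return A [TcrChannelStats-class].
#' @export
tcrChannelStats <- function(recording, events, params = tcrParams()) {
  stopifnot(is(recording, "EEGRecording"))
  sm <- smoothMovingAverage(recording, windowMs = params@smoothWindowMs,
                            stepMs = params@smoothStepMs)
  rownames(sm) <- recording@labels
  es <- epochAndWarp(sm, events, warpPoints = params@warpPoints)
  corr <- epochTemplateCorrelations(es)
  frac <- fractionCorrelated(corr, params@corrThreshold)
  arng <- amplitudeRange(es, params@rangeWindowFraction)
  bp <- findBreakingPoint(sort(arng))
  new("TcrChannelStats",
      condition = recording@condition, corr = corr, fraction = frac,
      arng = arng, breakingIndex = bp$index, breakingValue = bp$value,
      params = params)
}

#' Surrogate-null TCR statistics
#'
#' Repeats the first TCR stage with randomly timed events: for each
#' surrogate set, fixed-length epochs (one mean gait cycle) are cut at the
#' random event times, warped, correlated against their own template, and
#' the per-channel fraction above the correlation threshold is recorded.
#' The pooled correlations feed [estimateCorrelationThreshold()].
#'
#' @param recording an [EEGRecording-class].
#' @param nCycles experimental cycle count the surrogates are matched to.
#' @param params a [TcrParams-class].
#' @param seed seed for the surrogate ensemble.
#' @param ensemble optionally a precomputed [SurrogateEnsemble-class]
#'   (overrides \code{nCycles}/\code{seed}).
#' @return List with \code{fractions} (sets x channels matrix),
#'   \code{correlations} (pooled vector over sets, epochs and channels) and
#'   \code{ensemble}.
#' @export
tcrSurrogateStats <- function(recording, nCycles, params = tcrParams(),
                              seed = 1L, ensemble = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  if (is.null(ensemble))
    ensemble <- generateSurrogateEvents(
      ncol(recording@data), recording@fs, nCycles,
      nSets = params@nSurrogateSets, sectors = params@surrogateSectors,
      fraction = params@surrogateFraction, seed = seed)
  sm <- smoothMovingAverage(recording, windowMs = params@smoothWindowMs,
                            stepMs = params@smoothStepMs)
  rownames(sm) <- recording@labels
  fractions <- NULL
  pooled <- vector("list", length(ensemble@sets))
  for (s in seq_along(ensemble@sets)) {
    es <- epochAndWarp(sm, ensemble@sets[[s]],
                       warpPoints = params@warpPoints,
                       epochLenSamples = ensemble@epochLenSamples)
    corr <- epochTemplateCorrelations(es)
    fractions <- rbind(fractions,
                       fractionCorrelated(corr, params@corrThreshold))
    pooled[[s]] <- as.vector(corr)
  }
  list(fractions = fractions, correlations = unlist(pooled),
       ensemble = ensemble)
}

#' Select channels for rejection by template correlation
#'
#' A channel is flagged when, in at least one condition, more than
#' \code{fractionThreshold} of its epochs correlate with the template at
#' r above \code{corrThreshold} AND its amplitude range lies above that
#' condition's breaking point.  A channel flagged in either condition is
#' removed from both (union rule), so the cleaned conditions keep a common
#' channel set.
#'
#' @param statsA [TcrChannelStats-class] for the first condition.
#' @param statsB [TcrChannelStats-class] for the second condition, or NULL
#'   for single-condition use (with a warning).
#' @param params a [TcrParams-class]; defaults to the one inside
#'   \code{statsA}.
#' @return A [ChannelDecision-class] with reason code \code{TCR} and full
#'   evidence (fractions, amplitude ranges and breaking points per
#'   condition).
#' @export
selectChannelsTcr <- function(statsA, statsB = NULL, params = NULL) {
  stopifnot(is(statsA, "TcrChannelStats"))
  if (is.null(params)) params <- statsA@params
  labels <- names(statsA@fraction)
  condFlag <- function(st) {
    amp <- if (is.na(st@breakingValue)) rep(FALSE, length(st@arng))
    else st@arng > st@breakingValue
    st@fraction > params@fractionThreshold & amp
  }
  fA <- condFlag(statsA)
  if (is.null(statsB)) {
    warning("single-condition TCR selection: cross-condition union skipped")
    flagged <- fA
    evidence <- data.frame(label = labels, fractionA = statsA@fraction,
                           arngA = statsA@arng,
                           breakingPointA = statsA@breakingValue,
                           flaggedA = fA, row.names = NULL)
  } else {
    stopifnot(is(statsB, "TcrChannelStats"))
    if (!identical(labels, names(statsB@fraction)))
      stop("conditions were computed on different channel sets")
    fB <- condFlag(statsB)
    flagged <- fA | fB
    evidence <- data.frame(label = labels,
                           fractionA = statsA@fraction,
                           fractionB = statsB@fraction,
                           arngA = statsA@arng, arngB = statsB@arng,
                           breakingPointA = statsA@breakingValue,
                           breakingPointB = statsB@breakingValue,
                           flaggedA = fA, flaggedB = fB, row.names = NULL)
  }
  new("ChannelDecision", labels = labels, flagged = unname(flagged),
      reasons = lapply(flagged, function(f) if (f) "TCR" else character()),
      evidence = evidence, method = "TCR")
}
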