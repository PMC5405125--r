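#' @include AllClasses.R tcr-core.R spectral.R
NULL

#' Build an ICSet from a recording and an unmixing matrix
#'
#' Computes activations as \code{unmixing \%*\% data} and, when no mixing
#' matrix is supplied, inverts the unmixing matrix (pseudo-inverse for
#' non-square decompositions) to obtain the scalp maps.
#'
#' @param recording an [EEGRecording-class].
#' @param unmixing components x channels matrix.
#' @param mixing optional channels x components matrix.
#' @return An [ICSet-class].
#' @export
icSetFromUnmixing <- function(recording, unmixing, mixing = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  unmixing <- as.matrix(unmixing)
  if (ncol(unmixing) != nrow(recording@data))
    stop("unmixing must have one column per channel")
  if (is.null(mixing)) {
    if (nrow(unmixing) == ncol(unmixing)) mixing <- solve(unmixing)
    else {
      sv <- svd(unmixing)
      mixing <- sv$v %*% diag(1 / sv$d) %*% t(sv$u)   # pseudo-inverse
    }
  }
  ICSet(unmixing %*% recording@data, mixing, unmixing, recording@fs)
}

#' Template-correlation fractions for independent components
#'
#' Applies the first two TCR stages to component activation rows exactly as
#' to EEG channels - smoothing, event epoching, warping, template,
#' correlations, fraction above threshold.  No amplitude/breaking-point
#' stage is run: component activations are in arbitrary normalised units,
#' so amplitude is not comparable across components.
#'
#' @param icSet an [ICSet-class].
#' @param events [GaitEvents-class] or numeric 0-based sample times (for
#'   merged-condition data, merge the event series first).
#' @param params a [TcrParams-class].
#' @return Named per-component fractions in [0, 1].
#' @export
tcrScoreComponents <- function(icSet, events, params = tcrParams()) {
  stopifnot(is(icSet, "ICSet"))
  sm <- smoothMovingAverage(icSet@activations, icSet@fs,
                            windowMs = params@smoothWindowMs,
                            stepMs = params@smoothStepMs)
  rownames(sm) <- paste0("IC", seq_len(nrow(sm)))
  es <- epochAndWarp(sm, events, warpPoints = params@warpPoints)
  corr <- epochTemplateCorrelations(es)
  fractionCorrelated(corr, params@corrThreshold)
}

#' Component power spectra
#'
#' Welch spectra of every activation row, with the same 512 ms window /
#' 1,024 ms zero-pad convention as the channel band power.
#'
#' @param icSet an [ICSet-class].
#' @param ... passed to [welchPsd()].
#' @return List with \code{freq} and a components x freq \code{power}
#'   matrix.
#' @export
componentPsd <- function(icSet, ...) {
  stopifnot(is(icSet, "ICSet"))
  first <- welchPsd(icSet@activations[1L, ], icSet@fs, ...)
  power <- matrix(0, nrow(icSet@activations), length(first$freq))
  power[1L, ] <- first$power
  if (nrow(power) > 1L)
    for (k in 2L:nrow(power))
      power[k, ] <- welchPsd(icSet@activations[k, ], icSet@fs, ...)$power
  list(freq = first$freq, power = power)
}

#' Detect a physiologically relevant spectral peak
#'
#' Fits an aperiodic 1/f background as a line in log-log coordinates
#' (one robust refit excluding large positive residuals, so peaks do not
#' drag the background up) and reports any local maximum rising at least
#' \code{prominenceDb} above the background whose centre lies inside the
#' alpha, beta or gamma band.  Peaks confined to delta/theta do not count
#' as neural evidence.
#'
#' @param freq frequency axis, Hz (resolution should be <= 1 Hz).
#' @param power power spectrum (linear units).
#' @param bands qualifying bands; defaults to alpha/beta/gamma of
#'   [eegBands()].
#' @param prominenceDb required height above the aperiodic background, dB.
#' @param fitRange frequency range of the background fit, Hz.
#' @return List with \code{neural} (logical), \code{band}, \code{freqHz}
#'   and \code{prominenceDb} of the best qualifying peak (NA when none).
#' @export
detectSpectralPeak <- function(freq, power,
                               bands = eegBands()[c("alpha", "beta",
                                                    "gamma")],
                               prominenceDb = 3, fitRange = c(2, 80)) {
  keep <- freq >= fitRange[1L] & freq <= fitRange[2L] & power > 0
  if (sum(keep) < 8L) stop("spectrum too short for a background fit")
  lf <- log10(freq[keep])
  lp <- 10 * log10(power[keep])
  fit <- stats::lm.fit(cbind(1, lf), lp)
  resid <- lp - cbind(1, lf) %*% fit$coefficients
  ok <- resid < 2 * stats::sd(resid)       # drop peak bins, refit background
  fit <- stats::lm.fit(cbind(1, lf[ok]), lp[ok])
  resid <- as.vector(lp - cbind(1, lf) %*% fit$coefficients)
  f <- freq[keep]
  n <- length(resid)
  isMax <- c(FALSE, resid[2:(n - 1L)] >= resid[1:(n - 2L)] &
               resid[2:(n - 1L)] >= resid[3:n], FALSE)
  cand <- which(isMax & resid >= prominenceDb)
  out <- list(neural = FALSE, band = NA_character_, freqHz = NA_real_,
              prominenceDb = NA_real_)
  for (i in cand[order(resid[cand], decreasing = TRUE)]) {
    for (b in names(bands)) {
      if (f[i] >= bands[[b]][1L] && f[i] <= bands[[b]][2L]) {
        return(list(neural = TRUE, band = b, freqHz = f[i],
                    prominenceDb = resid[i]))
      }
    }
  }
  out
}

#' Scalp-map smoothness score
#'
#' Quantitative proxy for the visual "smooth/dipolar topography" check:
#' one minus the mean absolute difference of the map between neighbouring
#' sensors, normalised by twice the mean absolute map value.  A spatially
#' uniform map scores 1, a single-sensor delta map scores about 0, smooth
#' dipolar maps score high and channel-noise ("salt and pepper") maps score
#' low.
#'
#' @param map numeric vector, one value per channel (a mixing-matrix
#'   column).
#' @param positions channels x 2 (or 3) sensor coordinates.
#' @param nNeighbors neighbours per sensor used for the gradient.
#' @return Score in [0, 1].
#' @export
scalpMapSmoothness <- function(map, positions, nNeighbors = 6L) {
  map <- as.numeric(map)
  positions <- as.matrix(positions)
  if (nrow(positions) != length(map))
    stop("positions must have one row per channel")
  denom <- 2 * mean(abs(map))
  if (denom == 0) return(1)
  dmat <- as.matrix(stats::dist(positions))
  diag(dmat) <- Inf
  grads <- vapply(seq_along(map), function(i) {
    nb <- order(dmat[i, ])[seq_len(min(nNeighbors, length(map) - 1L))]
    mean(abs(map[i] - map[nb]))
  }, numeric(1))
  max(0, min(1, 1 - mean(grads) / denom))
}

#' Decide which independent components to reject
#'
#' A component is flagged when its template-correlation fraction exceeds
#' the threshold AND there is no evidence it carries neural content: no
#' qualifying alpha/beta/gamma spectral peak and a scalp map below the
#' smoothness cutoff.  Components with a qualifying spectral peak are
#' retained regardless of their fraction.
#'
#' @param fractions per-component TCR fractions ([tcrScoreComponents()]).
#' @param peaks list of per-component records from [detectSpectralPeak()],
#'   or a logical vector of qualifying-peak verdicts.
#' @param smoothness per-component scalp-map smoothness scores, or NULL
#'   (smoothness evidence then never rescues a component).
#' @param params a [TcrParams-class].
#' @param smoothnessCutoff maps at or above this score count as neural
#'   evidence (default calibrated on synthetic smooth neural maps).
#' @param override integer indices whose automatic flag is cleared after
#'   manual review.
#' @return An [ICDecision-class].
#' @export
selectComponents <- function(fractions, peaks, smoothness = NULL,
                             params = tcrParams(),
                             smoothnessCutoff = 0.76,
                             override = integer()) {
  k <- length(fractions)
  hasPeak <- if (is.logical(peaks)) peaks
  else vapply(peaks, function(p) isTRUE(p$neural), logical(1))
  if (is.null(smoothness)) smoothness <- rep(NA_real_, k)
  smooth <- !is.na(smoothness) & smoothness >= smoothnessCutoff
  neural <- hasPeak | smooth
  flagged <- fractions > params@fractionThreshold & !neural
  flagged[override] <- FALSE
  peakBand <- if (is.logical(peaks)) rep(NA_character_, k)
  else vapply(peaks, function(p) as.character(p$band), character(1))
  peakFreq <- if (is.logical(peaks)) rep(NA_real_, k)
  else vapply(peaks, function(p) as.numeric(p$freqHz), numeric(1))
  peakProm <- if (is.logical(peaks)) rep(NA_real_, k)
  else vapply(peaks, function(p) as.numeric(p$prominenceDb), numeric(1))
  new("ICDecision",
      flagged = unname(flagged),
      evidence = data.frame(
        component = seq_len(k), fraction = unname(fractions),
        fractionThreshold = params@fractionThreshold,
        hasPeak = hasPeak, peakBand = peakBand, peakFreqHz = peakFreq,
        peakProminenceDb = peakProm, smoothness = smoothness,
        smoothnessCutoff = smoothnessCutoff, neuralEvidence = neural,
        row.names = NULL),
      override = as.integer(override))
}

#' Remove flagged components by back-projection
#'
#' Subtracts the channel-space contribution of every flagged component,
#' \code{mixing[, flagged] \%*\% activations[flagged, ]}, from the
#' recording.  With nothing flagged the recording is returned unchanged;
#' the unflagged component subspace is preserved to float tolerance.
#'
#' @param recording the [EEGRecording-class] the decomposition was fit on.
#' @param icSet an [ICSet-class].
#' @param decision an [ICDecision-class] (or logical/integer component
#'   selection).
#' @return The cleaned [EEGRecording-class].
#' @export
removeComponentsAndBackproject <- function(recording, icSet, decision) {
  stopifnot(is(recording, "EEGRecording"), is(icSet, "ICSet"))
  flag <- if (is(decision, "ICDecision")) which(decision@flagged)
  else if (is.logical(decision)) which(decision)
  else as.integer(decision)
  if (nrow(icSet@mixing) != nrow(recording@data) ||
      ncol(icSet@activations) != ncol(recording@data))
    stop("decomposition dimensions do not match the recording")
  out <- recording
  if (length(flag))
    out@data <- recording@data -
      icSet@mixing[, flag, drop = FALSE] %*%
      icSet@activations[flag, , drop = FALSE]
  out
}
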