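#' @include AllClasses.R io-events.R
NULL

#' Design a linear-phase FIR high-pass filter
#'
#' Windowed-sinc (Hamming) high-pass whose -6 dB point sits at
#' \code{cutoffHz}.  The number of taps follows the Hamming transition-width
#' rule 3.3 / (transition bandwidth), forced odd so the group delay is an
#' integer number of samples; at 512 Hz with the default 0.2 Hz transition
#' this is a ~8,400-tap filter, flat (within +/-0.5 dB) above ~1.2 Hz.
#'
#' @param fs sampling rate, Hz.
#' @param cutoffHz -6 dB cutoff, Hz.
#' @param transitionHz transition bandwidth, Hz.
#' @param nTaps optional explicit tap count (forced odd).
#' @return Numeric vector of filter coefficients.
#' @export
designHighpass <- function(fs, cutoffHz = 1, transitionHz = 0.2,
                           nTaps = NULL) {
  if (is.null(nTaps)) nTaps <- ceiling(3.3 * fs / transitionHz)
  nTaps <- as.integer(nTaps)
  if (nTaps %% 2L == 0L) nTaps <- nTaps + 1L
  signal::fir1(nTaps - 1L, cutoffHz / (fs / 2), type = "high")
}

#' Frequency response of an FIR filter
#'
#' @param b filter coefficients.
#' @param freqsHz frequencies at which to evaluate, Hz.
#' @param fs sampling rate, Hz.
#' @return Complex response at each frequency (take \code{Mod()} for gain).
#' @export
firFrequencyResponse <- function(b, freqsHz, fs) {
  k <- seq_along(b) - 1L
  vapply(freqsHz,
         function(f) sum(b * exp(-2i * pi * f * k / fs)),
         complex(1))
}

## zero-phase application of a symmetric FIR: single pass, group-delay
## compensation, reflected-edge padding
applyFirZeroPhase <- function(b, x) {
  n <- length(x)
  d <- (length(b) - 1L) %/% 2L
  if (n <= length(b))
    stop("signal shorter than the filter (", length(b), " taps)")
  padL <- 2 * x[1L] - x[(d + 1L):2L]
  padR <- 2 * x[n] - x[(n - 1L):(n - d)]
  y <- signal::fftfilt(b, c(padL, x, padR))
  y[(2L * d + 1L):(2L * d + n)]
}

#' Zero-phase FIR high-pass filter
#'
#' Removes DC and slow drifts ahead of artifact screening.  The filter is
#' linear-phase and applied in a single pass with group-delay compensation
#' and reflected-edge padding, so the output is zero-phase.
#'
#' @param recording an [EEGRecording-class], numeric matrix
#'   (channels x samples) or vector.
#' @param fs sampling rate (taken from the recording when given one).
#' @param cutoffHz,transitionHz,nTaps passed to [designHighpass()].
#' @return Filtered object of the same type as the input.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 128))
#' y <- highpassFilter(x, fs = 128, nTaps = 257)
#' @export
highpassFilter <- function(recording, fs = NULL, cutoffHz = 1,
                           transitionHz = 0.2, nTaps = NULL) {
  applyPerChannel(recording, fs, function(x, fs) {
    b <- designHighpass(fs, cutoffHz, transitionHz, nTaps)
    applyFirZeroPhase(b, x)
  })
}

#' Notch out mains interference and its harmonics
#'
#' Cascade of zero-phase second-order IIR notches at the line frequency and
#' every harmonic below Nyquist.  Attenuation at each notch exceeds 30 dB
#' while the response 5 Hz away changes by less than 1 dB.
#'
#' @inheritParams highpassFilter
#' @param lineFreq mains frequency, Hz; must be below Nyquist.
#' @param bandwidthHz -3 dB notch width, Hz.
#' @param harmonics notch harmonics up to Nyquist as well?
#' @return Filtered object of the same type as the input.
#' @export
notchLineNoise <- function(recording, lineFreq, fs = NULL, bandwidthHz = 1,
                           harmonics = TRUE) {
  applyPerChannel(recording, fs, function(x, fs) {
    if (lineFreq >= fs / 2) stop("lineFreq must be below Nyquist")
    freqs <- if (harmonics)
      seq(lineFreq, fs / 2 - 1e-9, by = lineFreq) else lineFreq
    for (f0 in freqs) {
      w0 <- 2 * pi * f0 / fs
      r <- 1 - pi * bandwidthHz / fs
      b <- c(1, -2 * cos(w0), 1)
      a <- c(1, -2 * r * cos(w0), r^2)
      b <- b * sum(a) / sum(b)   # unit gain at DC
      x <- signal::filtfilt(signal::Arma(b = b, a = a), x)
    }
    x
  })
}

applyPerChannel <- function(recording, fs, fn) {
  if (is(recording, "EEGRecording")) {
    out <- recording
    out@data <- t(apply(recording@data, 1L, fn, fs = recording@fs))
    return(out)
  }
  if (is.matrix(recording)) {
    if (is.null(fs)) stop("fs required for matrix input")
    return(t(apply(recording, 1L, fn, fs = fs)))
  }
  if (is.null(fs)) stop("fs required for vector input")
  fn(as.numeric(recording), fs)
}

#' Conventional ("method 1") bad-channel screening
#'
#' The four standard criteria applied before any template-correlation step:
#' \enumerate{
#'   \item peak-to-peak magnitude below 30 uV (\code{LOW_RANGE}) or above
#'     3,000 uV (\code{HIGH_RANGE});
#'   \item per-channel kurtosis more than 5 standard deviations from the
#'     across-channel mean (\code{KURTOSIS});
#'   \item channels uncorrelated with their surroundings
#'     (\code{NEIGHBOR_CORR}): in 1 s non-overlapping windows, the maximum
#'     correlation with the 8 nearest sensors stays below \code{corrMin} in
#'     more than \code{badWindowFraction} of windows;
#'   \item standard-deviation outliers (\code{STD_OUTLIER}): channels above
#'     the knee of the ascending sorted SD curve that are also robust
#'     (median/MAD) outliers - an automated stand-in for visual inspection
#'     of the sorted SDs.
#' }
#'
#' @param recording an [EEGRecording-class] (>= 8 channels for the neighbor
#'   criterion).
#' @param positions sensor coordinates; defaults to the recording's.  When
#'   absent, criterion 3 is skipped with a warning.
#' @param lowUv,highUv magnitude bounds, uV.
#' @param kurtosisZ across-channel z-score bound for criterion 2.
#' @param robustKurtosis use median/MAD instead of mean/SD for the kurtosis
#'   z-score.
#' @param corrMin,badWindowFraction,windowSec,nNeighbors criterion-3 knobs.
#' @param sdZ robust z bound for criterion 4.
#' @return A [ChannelDecision-class] with per-criterion evidence.
#' @export
rejectChannelsMethod1 <- function(recording, positions = NULL,
                                  lowUv = 30, highUv = 3000,
                                  kurtosisZ = 5, robustKurtosis = FALSE,
                                  corrMin = 0.4, badWindowFraction = 0.01,
                                  windowSec = 1, nNeighbors = 8L,
                                  sdZ = 5) {
  stopifnot(is(recording, "EEGRecording"))
  data <- recording@data
  nc <- nrow(data)
  if (is.null(positions)) positions <- recording@positions

  rng <- apply(data, 1L, function(x) diff(range(x)))
  kurt <- apply(data, 1L, e1071::kurtosis, type = 2L)  # NaN for flat channels
  kz <- if (robustKurtosis)
    (kurt - stats::median(kurt, na.rm = TRUE)) /
      stats::mad(kurt, na.rm = TRUE)
  else (kurt - mean(kurt, na.rm = TRUE)) / stats::sd(kurt, na.rm = TRUE)

  badFrac <- rep(NA_real_, nc)
  if (is.null(positions)) {
    warning("no sensor positions: neighbor-correlation criterion skipped")
  } else if (nc < 8L) {
    warning("fewer than 8 channels: neighbor-correlation criterion skipped")
  } else {
    dmat <- as.matrix(stats::dist(positions))
    diag(dmat) <- Inf
    nb <- apply(dmat, 1L, function(d)
      order(d)[seq_len(min(nNeighbors, nc - 1L))])
    win <- max(2L, round(windowSec * recording@fs))
    nWin <- ncol(data) %/% win
    if (nWin < 1L) stop("recording shorter than one correlation window")
    bad <- matrix(FALSE, nc, nWin)
    for (w in seq_len(nWin)) {
      cols <- (w - 1L) * win + seq_len(win)
      cc <- suppressWarnings(stats::cor(t(data[, cols, drop = FALSE])))
      cc[!is.finite(cc)] <- 0
      for (ch in seq_len(nc))
        bad[ch, w] <- max(cc[ch, nb[, ch]]) < corrMin
    }
    badFrac <- rowMeans(bad)
  }

  sds <- apply(data, 1L, stats::sd)
  bp <- findBreakingPoint(sort(sds))
  sdRobustZ <- (sds - stats::median(sds)) / stats::mad(sds)
  sdFlag <- if (is.na(bp$value)) rep(FALSE, nc)
  else sds > bp$value & sdRobustZ > sdZ

  reasons <- vector("list", nc)
  for (ch in seq_len(nc)) {
    r <- character()
    if (rng[ch] < lowUv) r <- c(r, "LOW_RANGE")
    if (rng[ch] > highUv) r <- c(r, "HIGH_RANGE")
    if (is.finite(kz[ch]) && kz[ch] > kurtosisZ) r <- c(r, "KURTOSIS")
    if (!is.na(badFrac[ch]) && badFrac[ch] > badWindowFraction)
      r <- c(r, "NEIGHBOR_CORR")
    if (sdFlag[ch]) r <- c(r, "STD_OUTLIER")
    reasons[[ch]] <- r
  }
  new("ChannelDecision",
      labels = recording@labels,
      flagged = lengths(reasons) > 0L,
      reasons = reasons,
      evidence = data.frame(
        label = recording@labels, peakToPeakUv = rng,
        kurtosis = kurt, kurtosisZ = kz,
        lowCorrWindowFraction = badFrac,
        sdUv = sds, sdRobustZ = sdRobustZ,
        sdKneeUv = bp$value, row.names = NULL),
      method = "method1")
}
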