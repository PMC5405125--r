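#' @include AllClasses.R
NULL

#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 5-8, alpha 9-13, beta 14-30 and gamma 31-80 Hz.  The
#' integer figures label whole spectral bins at the ~1 Hz resolution set by
#' the 512 ms / 1,024 ms analysis convention: a bin belongs to the band its
#' centre frequency rounds to.  The returned integration edges therefore
#' sit half a bin outside the printed integers (delta [0.5, 4.5), theta
#' [4.5, 8.5), alpha [8.5, 13.5), beta [13.5, 30.5), gamma [30.5, 80.5)),
#' every bin from 1 to 80 Hz belongs to exactly one band, and band widths
#' are proportional to the printed bin counts (4, 4, 5, 17, 50).
#' \code{contiguous = FALSE} returns the literal printed edges instead.
#'
#' @param contiguous return rounding-rule boundaries (default) or the
#'   literal integer edges.
#' @return Named list of \code{c(low, high)} band edges in Hz.
#' @export
eegBands <- function(contiguous = TRUE) {
  if (contiguous)
    list(delta = c(0.5, 4.5), theta = c(4.5, 8.5), alpha = c(8.5, 13.5),
         beta = c(13.5, 30.5), gamma = c(30.5, 80.5))
  else
    list(delta = c(1, 4), theta = c(5, 8), alpha = c(9, 13),
         beta = c(14, 30), gamma = c(31, 80))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with 512 ms Hamming windows zero-padded to
#' 1,024 ms and 50 percent overlap (all configurable).  One-sided density in
#' uV^2/Hz; summing \code{power * df} over all bins recovers (approximately)
#' the signal variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param windowSec window length, seconds.
#' @param padSec zero-padded FFT length, seconds.
#' @param overlap fractional window overlap.
#' @return List with \code{freq} (Hz) and \code{power} (uV^2/Hz).
#' @export
welchPsd <- function(x, fs, windowSec = 0.512, padSec = 1.024,
                     overlap = 0.5) {
  x <- as.numeric(x)
  L <- round(windowSec * fs)
  if (length(x) < L) stop("signal shorter than one window")
  nfft <- max(L, round(padSec * fs))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L))
  norm <- fs * sum(w^2)
  nHalf <- nfft %/% 2L
  acc <- numeric(nHalf + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    sp <- stats::fft(c(seg, numeric(nfft - L)))
    acc <- acc + Mod(sp[seq_len(nHalf + 1L)])^2 / norm
  }
  p <- acc / length(starts)
  p[2:nHalf] <- 2 * p[2:nHalf]    # one-sided
  list(freq = (0:nHalf) * fs / nfft, power = p)
}

#' Band-integrated absolute power
#'
#' Integrates the Welch spectrum ([welchPsd()], 512 ms windows zero-padded
#' to 1,024 ms) over the canonical EEG bands.  Power is reported in uV^2
#' (band-integrated spectral power, not a density).
#'
#' @param x numeric vector, channels x samples matrix, or
#'   [EEGRecording-class].
#' @param fs sampling rate, Hz.
#' @param bands named list of \code{c(low, high)} edges; see [eegBands()].
#' @param ... passed to [welchPsd()].
#' @return Named vector of band powers (or a channels x bands matrix).
#' @examples
#' t <- seq(0, 10, by = 1 / 256)
#' bandAbsolutePower(sin(2 * pi * 10 * t), fs = 256)
#' @export
bandAbsolutePower <- function(x, fs = NULL, bands = eegBands(), ...) {
  if (is(x, "EEGRecording")) {
    fs <- x@fs
    x <- x@data
  }
  if (is.null(fs)) stop("fs required")
  hi <- max(vapply(bands, max, numeric(1)))
  if (hi > fs / 2) stop("band edge ", hi, " Hz is above Nyquist")
  one <- function(v) {
    psd <- welchPsd(v, fs, ...)
    df <- psd$freq[2L] - psd$freq[1L]
    vapply(bands, function(b)          # half-open bins: each counted once
      sum(psd$power[psd$freq >= b[1L] & psd$freq < b[2L]]) * df,
      numeric(1))
  }
  if (is.matrix(x)) t(apply(x, 1L, one)) else one(as.numeric(x))
}

#' Median band power across channels
#'
#' Per-band median of [bandAbsolutePower()] over a channel subset; the
#' summary used to compare rejected against retained channels.
#'
#' @param recording an [EEGRecording-class].
#' @param channels channel indices (default all).
#' @param bands named band list.
#' @return Named vector of median band powers, uV^2.
#' @export
medianBandPower <- function(recording, channels = NULL,
                            bands = eegBands()) {
  stopifnot(is(recording, "EEGRecording"))
  if (is.null(channels)) channels <- seq_len(nrow(recording@data))
  bp <- bandAbsolutePower(recording@data[channels, , drop = FALSE],
                          recording@fs, bands)
  apply(bp, 2L, stats::median)
}

#' Gait-locked amplitude map for one channel
#'
#' RMS-smoothed instantaneous amplitude of a channel, cut into epochs
#' aligned to the contact events: the diagnostic image in which a
#' motion-artifact channel shows a stereotyped high-amplitude stripe shortly
#' after every heel strike, and a cleaned channel does not.
#'
#' @param recording an [EEGRecording-class].
#' @param events [GaitEvents-class] (contact events) or numeric 0-based
#'   samples.
#' @param channel channel index or label.
#' @param windowSec event-relative window \code{c(start, end)}, seconds.
#' @param rmsWindowMs RMS smoothing window, ms.
#' @return A [GaitAmplitudeMap-class].
#' @export
gaitLockedAmplitudeMap <- function(recording, events, channel,
                                   windowSec = c(-0.2, 1.0),
                                   rmsWindowMs = 50) {
  stopifnot(is(recording, "EEGRecording"))
  if (is.character(channel))
    channel <- match(channel, recording@labels)
  x <- recording@data[channel, ]
  fs <- recording@fs
  if (is(events, "GaitEvents")) events <- events@times
  w <- max(1L, round(rmsWindowMs / 1000 * fs))
  rms <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2L))
  lo <- round(windowSec[1L] * fs)
  hi <- round(windowSec[2L] * fs)
  rows <- list()
  for (e in events) {
    idx <- e + 1L + (lo:hi)       # 0-based event -> 1-based index
    if (idx[1L] < 1L || idx[length(idx)] > length(x)) next
    rows[[length(rows) + 1L]] <- as.numeric(rms[idx])
  }
  if (!length(rows)) stop("no event window fits inside the recording")
  map <- do.call(rbind, rows)
  map[!is.finite(map)] <- 0       # filter NA at the very edges
  new("GaitAmplitudeMap", map = map, time = (lo:hi) / fs,
      meanTrace = colMeans(map),
      channel = recording@labels[channel])
}
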