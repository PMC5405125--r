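#' @include AllClasses.R
NULL

#' Detect gait events from vertical ground reaction force
#'
#' Initial foot contacts are marked where the force rises above the threshold
#' (15 N by default) and toe-offs where it drops back below.  Crossings
#' within \code{debounceMs} of the previous accepted crossing of the same
#' direction are ignored (sensor chatter at the threshold), and alternation
#' is enforced: a toe-off is only accepted after a contact and vice versa.
#'
#' @param force a [ForceSeries-class], or a numeric vector with \code{fs}.
#' @param thresholdNewtons force threshold, newtons.
#' @param fs sampling rate, required when \code{force} is a bare vector.
#' @param foot \code{"right"} or \code{"left"}; sets the event labels
#'   (RHS/RTO or LHS/LTO).
#' @param debounceMs refractory period per crossing direction, ms.
#' @return A [GaitEvents-class] with contact and toe-off events (0-based
#'   sample indices).  Empty when the force never crosses the threshold.
#' @examples
#' f <- numeric(2000); f[513:820] <- 100
#' detectGaitEvents(ForceSeries(f, 512))
#' @export
detectGaitEvents <- function(force, thresholdNewtons = 15, fs = NULL,
                             foot = c("right", "left"), debounceMs = 100) {
  foot <- match.arg(foot)
  if (is(force, "ForceSeries")) {
    fs <- force@fs
    x <- force@samples
  } else {
    if (is.null(fs)) stop("fs required when force is a bare vector")
    x <- as.numeric(force)
  }
  if (!length(x)) stop("force series is empty")
  if (any(!is.finite(x))) stop("force contains non-finite samples")
  lab <- if (foot == "right") c("RHS", "RTO") else c("LHS", "LTO")
  above <- x >= thresholdNewtons
  d <- diff(above)
  up <- which(d == 1L)        # R index i: crossing at sample i+1 (1-based)
  down <- which(d == -1L)
  debounce <- function(idx) {
    if (length(idx) < 2L) return(idx)
    keep <- idx[1L]
    for (i in idx[-1L]) if (i - keep[length(keep)] > debounceMs / 1000 * fs)
      keep <- c(keep, i)
    keep
  }
  up <- debounce(up)
  down <- debounce(down)
  ev <- rbind(data.frame(t = up, lab = rep(lab[1L], length(up))),
              data.frame(t = down, lab = rep(lab[2L], length(down))))
  ev <- ev[order(ev$t), , drop = FALSE]
  ## enforce contact -> toe-off alternation, starting at a contact
  keep <- logical(nrow(ev))
  expect <- lab[1L]
  for (i in seq_len(nrow(ev))) {
    if (ev$lab[i] == expect) {
      keep[i] <- TRUE
      expect <- if (expect == lab[1L]) lab[2L] else lab[1L]
    }
  }
  ev <- ev[keep, , drop = FALSE]
  GaitEvents(ev$t, ev$lab)  # diff index == 0-based crossing sample
}

#' Read / write event tables
#'
#' Events are stored as tab-separated text with the header
#' \code{sample<TAB>label}; sample indices are 0-based.
#'
#' @param path file path.
#' @return \code{readEvents} returns a [GaitEvents-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeEvents(GaitEvents(c(10, 400), c("RHS", "RHS")), tf)
#' readEvents(tf)
#' @export
readEvents <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("numeric", "character"))
  if (!all(c("sample", "label") %in% names(tab)))
    stop("event file must have columns 'sample' and 'label'")
  if (is.unsorted(tab$sample, strictly = TRUE))
    stop("event times must be strictly increasing; offending file: ", path)
  GaitEvents(tab$sample, tab$label)
}

#' @rdname readEvents
#' @param events a [GaitEvents-class].
#' @export
writeEvents <- function(events, path) {
  stopifnot(is(events, "GaitEvents"))
  utils::write.table(
    data.frame(sample = events@times, label = events@labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write EEG recordings
#'
#' Two on-disk formats are supported.  \code{"flat"} is a float64
#' little-endian channels-major binary file with a JSON sidecar
#' (\code{<path>.json}) holding the sampling rate, labels, positions and
#' condition; it round-trips exactly.  \code{"bdf"} is the 24-bit BioSemi
#' data format (BDF); values round-trip to within one quantisation step of
#' the per-channel physical/digital scaling declared in the header.
#'
#' @param path file path.
#' @param format \code{"flat"} or \code{"bdf"}; default guesses from the
#'   file extension.
#' @return \code{readRecording} returns an [EEGRecording-class].
#' @examples
#' rec <- EEGRecording(matrix(rnorm(1024), 2), fs = 256)
#' tf <- tempfile(fileext = ".dat")
#' writeRecording(rec, tf)
#' all.equal(eegData(readRecording(tf)), eegData(rec))
#' @export
readRecording <- function(path, format = c("auto", "flat", "bdf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bdf$", path, ignore.case = TRUE)) "bdf" else "flat"
  if (format == "bdf") return(readBDF(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- meta$nChannels * meta$nSamples
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(x) != n) stop("flat recording truncated: ", path)
  pos <- NULL
  if (!is.null(meta$positions) && length(meta$positions))
    pos <- matrix(unlist(meta$positions), nrow = meta$nChannels)
  EEGRecording(matrix(x, nrow = meta$nChannels), meta$fs,
               labels = meta$labels, positions = pos,
               condition = if (is.null(meta$condition)) "" else meta$condition)
}

#' @rdname readRecording
#' @param recording an [EEGRecording-class].
#' @export
writeRecording <- function(recording, path,
                           format = c("auto", "flat", "bdf")) {
  stopifnot(is(recording, "EEGRecording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bdf$", path, ignore.case = TRUE)) "bdf" else "flat"
  if (format == "bdf") return(writeBDF(recording, path))
  meta <- list(formatVersion = 1L, dtype = "float64le",
               order = "channels-major",
               nChannels = nrow(recording@data),
               nSamples = ncol(recording@data),
               fs = recording@fs, units = "uV",
               labels = recording@labels,
               positions = recording@positions,
               condition = recording@condition)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(recording@data), con, size = 8L, endian = "little")
  invisible(path)
}

## ---- minimal BDF (BioSemi 24-bit) reader/writer -------------------------
## Fixed-layout header (256 bytes + 256 per channel), then data records of
## 24-bit little-endian signed ints, channel-blocked.  One record per second.

padField <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

writeBDF <- function(recording, path) {
  data <- recording@data
  ns <- nrow(data)
  fs <- recording@fs
  if (fs != round(fs)) stop("BDF export requires an integer sampling rate")
  recLen <- as.integer(fs)                      # 1 s data records
  nRec <- ceiling(ncol(data) / recLen)
  pad <- nRec * recLen - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, ns, pad))
  physMin <- floor(apply(data, 1L, min))
  physMax <- ceiling(apply(data, 1L, max))
  physMax <- pmax(physMax, physMin + 1)
  digMin <- -8388608; digMax <- 8388607
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(padField(x, width),
                                            collapse = ""),
                                     con, eos = NULL)
  writeBin(as.raw(255L), con)
  writeChar("BIOSEMI", con, eos = NULL)
  wr("gaitTCR synthetic/exported recording", 80)
  wr(recording@condition, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8)
  wr("24BIT", 44)
  wr(as.character(nRec), 8)
  wr("1", 8)                                     # record duration, s
  wr(as.character(ns), 4)
  wr(recording@labels, 16)
  wr(rep("active electrode", ns), 80)
  wr(rep("uV", ns), 8)
  wr(as.character(physMin), 8)
  wr(as.character(physMax), 8)
  wr(rep(as.character(digMin), ns), 8)
  wr(rep(as.character(digMax), ns), 8)
  wr(rep("", ns), 80)
  wr(rep(as.character(recLen), ns), 8)
  wr(rep("", ns), 32)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    cols <- (r - 1L) * recLen + seq_len(recLen)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, cols] - physMin[ch]) / scale[ch]) + digMin
      dig <- pmin(pmax(dig, digMin), digMax)
      u <- as.integer(dig + 8388608)             # offset to unsigned 24-bit
      b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
      writeBin(as.raw(b), con)
    }
  }
  invisible(path)
}

readBDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id0 <- readBin(con, "raw", 1L)
  magic <- readChar(con, 7L, useBytes = TRUE)
  if (as.integer(id0) != 255L || magic != "BIOSEMI")
    stop("not a BDF file (bad magic): ", path)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(80)
  condition <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  rd(8)
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  recLen <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(recLen)) != 1L)
    stop("mixed per-channel record lengths are not supported")
  recLen <- recLen[1L]
  scale <- (physMax - physMin) / (digMax - digMin)
  data <- matrix(0, ns, nRec * recLen)
  for (r in seq_len(nRec)) {
    raw <- readBin(con, "raw", 3L * ns * recLen)
    if (length(raw) < 3L * ns * recLen) stop("BDF data truncated: ", path)
    m <- matrix(as.integer(raw), nrow = 3L)
    u <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    dig <- u - 8388608L
    cols <- (r - 1L) * recLen + seq_len(recLen)
    for (ch in seq_len(ns)) {
      seg <- dig[(ch - 1L) * recLen + seq_len(recLen)]
      data[ch, cols] <- (seg - digMin[ch]) * scale[ch] + physMin[ch]
    }
  }
  EEGRecording(data, recLen, labels = labels, condition = condition)
}

#' Serialise a decision record to JSON
#'
#' Writes every flagged channel or component with its reason codes and the
#' full numeric evidence table, so a rejection can be audited without
#' re-running the pipeline.
#'
#' @param decision a [ChannelDecision-class] or [ICDecision-class].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeReport <- function(decision, path) {
  if (is(decision, "ChannelDecision")) {
    out <- list(
      type = "channels", method = decision@method,
      nFlagged = sum(decision@flagged),
      flagged = decision@labels[decision@flagged],
      reasons = stats::setNames(decision@reasons, decision@labels),
      evidence = decision@evidence)
  } else if (is(decision, "ICDecision")) {
    out <- list(
      type = "components",
      nFlagged = sum(decision@flagged),
      flagged = which(decision@flagged),
      override = decision@override,
      evidence = decision@evidence)
  } else stop("unsupported decision object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
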