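## EDF (European Data Format) 16-bit reader/writer.
## Only the features the pipeline needs: one continuous multichannel signal,
## physical unit microvolts, no annotation channels.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = "-")
}

edfNum <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  while (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = max(1L, nchar(s) - (nchar(s) - width) - 2L), width = 1)
    if (nchar(s) <= width) break
    s <- formatC(x, format = "e", digits = 1, width = 1)
    break
  }
  if (nchar(s) > width) stop("numeric field does not fit EDF header: ", x)
  edfPad(s, width)
}

readChars <- function(con, n) readBin(con, "raw", n = n) |> rawToChar()

#' Write an EEG recording to an EDF file
#'
#' Signals are stored as 16-bit integers; the physical range declared in the
#' header is the channel's data range, so the quantization step is
#' `range / 65535`. Channel order is preserved. Data records are 1 s long
#' when the sample count allows it, otherwise a single record holds the
#' whole signal.
#'
#' @param rec an [EEGRecording-class]; voltages in microvolts.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  x <- eegData(rec)
  if (nrow(x) == 0L) stop("recording has no channels")
  ns <- nrow(x)
  n <- ncol(x)
  fs <- samplingRate(rec)
  if (n == 0L) stop("recording has no samples")
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0L) {
    recDur <- 1
    spr <- round(fs)
  } else {
    recDur <- n / fs
    spr <- n
  }
  nRec <- n / spr
  physMin <- apply(x, 1L, min)
  physMax <- apply(x, 1L, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMax[flat] + 1
  ## use the header-representable values for scaling so that the round trip
  ## is exact to within one digitization step
  physMin <- as.numeric(vapply(physMin, edfNum, ""))
  physMax <- as.numeric(vapply(physMax, edfNum, ""))
  digMin <- -32768L
  digMax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edfPad("0", 8L))
  wr(edfPad(paste(subjectId(rec), session(rec)), 80L))
  wr(edfPad("qeeg", 80L))
  wr(edfPad("01.01.00", 8L))
  wr(edfPad("00.00.00", 8L))
  wr(edfPad(as.character(256L + 256L * ns), 8L))
  wr(edfPad("", 44L))
  wr(edfPad(as.character(nRec), 8L))
  wr(edfNum(recDur, 8L))
  wr(edfPad(as.character(ns), 4L))
  labs <- channelNames(rec)
  for (s in labs) wr(edfPad(s, 16L))
  for (s in labs) wr(edfPad("AgAgCl electrode", 80L))
  for (s in labs) wr(edfPad("uV", 8L))
  for (v in physMin) wr(edfNum(v, 8L))
  for (v in physMax) wr(edfNum(v, 8L))
  for (s in labs) wr(edfPad(as.character(digMin), 8L))
  for (s in labs) wr(edfPad(as.character(digMax), 8L))
  for (s in labs) wr(edfPad("", 80L))
  for (s in labs) wr(edfPad(as.character(spr), 8L))
  for (s in labs) wr(edfPad("", 32L))

  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      d <- round((x[ch, idx] - physMin[ch]) * scale[ch]) + digMin
      d <- pmin(pmax(d, digMin), digMax)
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EEG recording from an EDF/EDF+ file
#'
#' Signal values are converted to physical units (microvolts) using the
#' header's physical/digital ranges. Channel order follows the file.
#'
#' @param path path to an EDF file.
#' @param requireChannels channel labels that must be present (matching is
#'   case-insensitive and whitespace-stripped); use `NULL` to skip the
#'   check. Defaults to [requiredChannels()].
#' @return An [EEGRecording-class]. The subject id and session are recovered
#'   from the patient identification field when it has the form
#'   `"<subject> <T0|T1>"`, as written by [writeEDF()].
#' @export
readEDF <- function(path, requireChannels = requiredChannels()) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- trimws(readChars(con, 8L))
  patient <- trimws(readChars(con, 80L))
  readChars(con, 80L)                      # recording id
  readChars(con, 16L)                      # start date/time
  headerBytes <- suppressWarnings(as.integer(trimws(readChars(con, 8L))))
  readChars(con, 44L)
  nRec <- suppressWarnings(as.integer(trimws(readChars(con, 8L))))
  recDur <- suppressWarnings(as.numeric(trimws(readChars(con, 8L))))
  ns <- suppressWarnings(as.integer(trimws(readChars(con, 4L))))
  if (!identical(version, "0") || is.na(headerBytes) || is.na(nRec) ||
      is.na(recDur) || is.na(ns) || ns <= 0L || recDur <= 0)
    stop("malformed EDF header in ", path)
  rdChar <- function(w) vapply(seq_len(ns), function(i) trimws(readChars(con, w)), "")
  rdNum <- function(w) suppressWarnings(as.numeric(rdChar(w)))
  labels <- rdChar(16L)
  rdChar(80L)                              # transducer
  rdChar(8L)                               # physical dimension
  physMin <- rdNum(8L)
  physMax <- rdNum(8L)
  digMin <- rdNum(8L)
  digMax <- rdNum(8L)
  rdChar(80L)                              # prefiltering
  spr <- rdNum(8L)
  rdChar(32L)
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)) ||
      any(spr <= 0) || any(digMax <= digMin))
    stop("malformed EDF signal headers in ", path)

  x <- matrix(0, nrow = ns, ncol = nRec * spr[1L])
  if (length(unique(spr)) != 1L)
    stop("signals with differing sampling rates are not supported")
  spr <- spr[1L]
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr, size = 2L,
                   signed = TRUE, endian = "little")
      if (length(d) < spr) stop("truncated EDF data in ", path)
      x[ch, idx] <- (d - digMin[ch]) * scale[ch] + physMin[ch]
    }
  }
  fs <- spr / recDur
  parts <- strsplit(patient, "\\s+")[[1L]]
  sess <- if (length(parts) >= 2L && parts[2L] %in% c("T0", "T1"))
    parts[2L] else "T0"
  sid <- if (length(parts) >= 1L && nzchar(parts[1L])) parts[1L] else "unknown"
  rec <- EEGRecording(x, fs = fs, channels = labels,
                      subjectId = sid, session = sess)
  if (!is.null(requireChannels)) checkRequiredChannels(rec, requireChannels)
  rec
}
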