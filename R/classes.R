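#' @include qeeg-package.R
NULL

## ---- channel conventions ---------------------------------------------------

#' Electrodes required by the affected-hemisphere analysis
#'
#' The pipeline analyzes the central (C3/C4), parietal (P3/P4) and occipital
#' (O1/O2) electrodes of the 10-20 system. By convention odd-numbered
#' electrodes are left-hemispheric.
#'
#' @return Character vector of the six required channel labels.
#' @export
#' @examples
#' requiredChannels()
requiredChannels <- function() c("C3", "C4", "P3", "P4", "O1", "O2")

#' Normalize a 10-20 channel label
#'
#' Matching is case-insensitive and whitespace-stripped.
#'
#' @param x character vector of labels.
#' @return Normalized labels (upper case, no surrounding whitespace).
#' @export
normalizeChannelLabel <- function(x) toupper(trimws(as.character(x)))

## ---- EEGRecording -----------------------------------------------------------

#' EEGRecording: a multi-channel resting-state EEG recording
#'
#' Voltage values are in microvolts, stored channel-by-sample. The channel
#' order is preserved by all readers and writers.
#'
#' @slot subjectId subject identifier.
#' @slot session recording session, `"T0"` (baseline) or `"T1"` (post
#'   treatment).
#' @slot fs sampling frequency in Hz.
#' @slot data numeric matrix, channels x samples, rownames are 10-20 labels.
#' @export
setClass("EEGRecording",
  representation(subjectId = "character", session = "character",
                 fs = "numeric", data = "matrix"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (!object@session %in% c("T0", "T1"))
    msg <- c(msg, "session must be 'T0' or 'T1'")
  ch <- rownames(object@data)
  if (is.null(ch) || anyNA(ch) || any(ch == ""))
    msg <- c(msg, "data must have channel labels as rownames")
  else if (anyDuplicated(normalizeChannelLabel(ch)))
    msg <- c(msg, "channel labels must be unique")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data numeric matrix, channels x samples (rownames taken as labels
#'   unless `channels` is given).
#' @param fs sampling frequency in Hz.
#' @param channels channel labels; defaults to `rownames(data)`.
#' @param subjectId subject identifier.
#' @param session `"T0"` or `"T1"`.
#' @return An [EEGRecording-class] object.
#' @export
#' @examples
#' x <- matrix(rnorm(6 * 100), 6, dimnames = list(requiredChannels(), NULL))
#' rec <- EEGRecording(x, fs = 100)
#' nSamples(rec)
EEGRecording <- function(data, fs, channels = rownames(data),
                         subjectId = "s01", session = "T0") {
  data <- as.matrix(data)
  if (is.null(channels))
    stop("channel labels are required (rownames of `data` or `channels`)")
  rownames(data) <- normalizeChannelLabel(channels)
  new("EEGRecording", subjectId = as.character(subjectId),
      session = as.character(session), fs = as.numeric(fs), data = data)
}

#' @rdname EEGRecording
#' @param object,x an `EEGRecording`.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname EEGRecording
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname EEGRecording
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname EEGRecording
#' @export
setGeneric("session", function(x) standardGeneric("session"))
#' @rdname EEGRecording
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EEGRecording
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname EEGRecording
#' @export
setMethod("channelNames", "EEGRecording", function(x) rownames(x@data))
#' @rdname EEGRecording
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)
#' @rdname EEGRecording
#' @export
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname EEGRecording
#' @export
setMethod("session", "EEGRecording", function(x) x@session)
#' @rdname EEGRecording
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s' session %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    object@subjectId, object@session, nrow(object@data), ncol(object@data),
    object@fs, ncol(object@data) / object@fs))
  cat("  channels:", paste(rownames(object@data), collapse = ", "), "\n")
})

#' Check that a recording carries the channels the pipeline needs
#'
#' @param rec an [EEGRecording-class].
#' @param channels required labels, default [requiredChannels()].
#' @return Invisibly `TRUE`; otherwise an error naming the absent labels.
#' @export
checkRequiredChannels <- function(rec, channels = requiredChannels()) {
  have <- normalizeChannelLabel(channelNames(rec))
  want <- normalizeChannelLabel(channels)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("recording '", subjectId(rec), "' is missing required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

## ---- EpochSet ---------------------------------------------------------------

#' EpochSet: the artifact-free segments selected for analysis
#'
#' Holds the epochs (channels x samples matrices, all the same shape) cut
#' from one preprocessed recording; the default pipeline keeps five 4-s
#' epochs (20 s of signal).
#'
#' @slot subjectId subject identifier.
#' @slot session `"T0"` or `"T1"`.
#' @slot fs sampling frequency in Hz.
#' @slot epochs list of channels x samples matrices.
#' @slot epochLength epoch length in seconds.
#' @export
setClass("EpochSet",
  representation(subjectId = "character", session = "character",
                 fs = "numeric", epochs = "list", epochLength = "numeric"))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (!length(object@epochs)) msg <- c(msg, "at least one epoch is required")
  dims <- unique(lapply(object@epochs, dim))
  if (length(dims) > 1L) msg <- c(msg, "all epochs must share dimensions")
  n <- ncol(object@epochs[[1L]])
  if (abs(n - object@epochLength * object@fs) > 0.5)
    msg <- c(msg, "epoch sample count does not match epochLength * fs")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#' @param epochs list of channels x samples matrices.
#' @param fs sampling frequency (Hz).
#' @param epochLength epoch length (s).
#' @param subjectId,session identifiers, as for [EEGRecording()].
#' @return An [EpochSet-class].
#' @export
EpochSet <- function(epochs, fs, epochLength = ncol(epochs[[1L]]) / fs,
                     subjectId = "s01", session = "T0") {
  new("EpochSet", subjectId = as.character(subjectId),
      session = as.character(session), fs = as.numeric(fs),
      epochs = epochs, epochLength = as.numeric(epochLength))
}

#' @rdname EpochSet
#' @param x an `EpochSet`.
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname EpochSet
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname EpochSet
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname EpochSet
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
#' @rdname EpochSet
#' @export
setMethod("session", "EpochSet", function(x) x@session)
#' @rdname EpochSet
#' @export
setMethod("channelNames", "EpochSet", function(x) rownames(x@epochs[[1L]]))

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet '%s' session %s: %d epoch(s) of %g s, %d channel(s) @ %g Hz\n",
              object@subjectId, object@session, length(object@epochs),
              object@epochLength, nrow(object@epochs[[1L]]), object@fs))
})
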