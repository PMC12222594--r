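# Generics shared across classes.

#' Sampling rate accessor
#' @param x an object with a sampling rate
#' @return sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel label accessor
#' @param x an object with channels
#' @return character vector of channel labels
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Trim recording/envelope edges
#'
#' Discards the first and last \code{seconds} of data (filter warm-up); for
#' trigger sequences the indices are re-expressed in trimmed coordinates and
#' out-of-span triggers dropped.
#'
#' @param x a ContinuousRecording, OnsetEnvelope or TriggerSequence
#' @param seconds seconds to discard at each edge (default 1)
#' @param length for TriggerSequence: original series length in samples,
#'   needed to drop triggers in the trailing edge
#' @return the trimmed object
#' @export
setGeneric("trimEdges", function(x, seconds = 1, length = NULL) standardGeneric("trimEdges"))

#' @rdname samplingRate
setMethod("samplingRate", "ContinuousRecording", function(x) x@fs)
#' @rdname samplingRate
setMethod("samplingRate", "OnsetEnvelope", function(x) x@fs)
#' @rdname samplingRate
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname samplingRate
setMethod("samplingRate", "Waveform", function(x) x@fs)
#' @rdname samplingRate
setMethod("samplingRate", "TriggerSequence", function(x) x@fs)

#' @rdname channelNames
setMethod("channelNames", "ContinuousRecording", function(x) x@channels)
#' @rdname channelNames
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @rdname channelNames
setMethod("channelNames", "Waveform", function(x) x@channels)

#' Matrix/array accessors
#'
#' \code{recMatrix} returns the channels x samples matrix of a recording,
#' \code{envValues} the sample vector of an envelope, \code{epochArray} the
#' time x channels x sweeps array, \code{waveMatrix} the channels x time
#' matrix of a waveform, \code{wpssValues} the frequencies x time WPSS
#' matrix, and \code{modelWeights} the lags x channels weight matrix.
#'
#' @param x the object
#' @return the underlying numeric data
#' @name accessors
NULL

#' @rdname accessors
#' @export
recMatrix <- function(x) { stopifnot(is(x, "ContinuousRecording")); x@data }
#' @rdname accessors
#' @export
envValues <- function(x) { stopifnot(is(x, "OnsetEnvelope")); x@values }
#' @rdname accessors
#' @export
epochArray <- function(x) { stopifnot(is(x, "EpochSet")); x@data }
#' @rdname accessors
#' @export
waveMatrix <- function(x) { stopifnot(is(x, "Waveform")); x@data }
#' @rdname accessors
#' @export
wpssValues <- function(x) { stopifnot(is(x, "WpssMap")); x@values }
#' @rdname accessors
#' @export
modelWeights <- function(x) { stopifnot(is(x, "LinearModel")); x@weights }

#' Time axis of a waveform or epoch set (ms relative to trigger)
#' @param x a Waveform or EpochSet
#' @return numeric vector of times in ms
#' @export
timesMs <- function(x) {
  if (is(x, "Waveform")) return(x@timesMs)
  if (is(x, "EpochSet")) return(x@sampleOffsets / x@fs * 1000)
  stop("no time axis for this object")
}

#' Accepted-sweep indices of an EpochSet
#' @param x an EpochSet
#' @return integer indices of sweeps not marked as artifacts
#' @export
acceptedSweeps <- function(x) { stopifnot(is(x, "EpochSet")); which(x@accepted) }
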