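# Minimal EEG conditioning on clean data: zero-phase Butterworth filtering,
# decimation, re-referencing, per-subject normalization.  All filters are
# 3rd-order Butterworth designs applied forward and backward.

.filterRows <- function(rec, bt) {
  out <- t(apply(rec@data, 1, function(ch) signal::filtfilt(bt, ch)))
  rec@data <- out
  rec
}

#' Zero-phase band-pass filter
#'
#' 3rd-order Butterworth band-pass (defaults 1-45 Hz) applied via forward and
#' backward passes to every channel.
#'
#' @param rec a [ContinuousRecording-class]
#' @param loHz,hiHz band edges, Hz; \code{hiHz} must be below fs/2
#' @return the filtered recording
#' @export
bandpassFilter <- function(rec, loHz = 1, hiHz = 45) {
  stopifnot(is(rec, "ContinuousRecording"))
  if (hiHz >= rec@fs / 2) stop("bandpassFilter: upper edge must be below fs/2")
  bt <- signal::butter(3, c(loHz, hiHz) / (rec@fs / 2), type = "pass")
  .filterRows(rec, bt)
}

#' Zero-phase low-pass filter
#'
#' 3rd-order Butterworth low-pass (default 30 Hz, the ERP smoothing cutoff)
#' applied via forward and backward passes to every channel.
#'
#' @param rec a [ContinuousRecording-class]
#' @param cutoffHz cutoff frequency, Hz; must be below fs/2
#' @return the filtered recording
#' @export
lowpassFilter <- function(rec, cutoffHz = 30) {
  stopifnot(is(rec, "ContinuousRecording"))
  if (cutoffHz >= rec@fs / 2) stop("lowpassFilter: cutoff must be below fs/2")
  bt <- signal::butter(3, cutoffHz / (rec@fs / 2))
  .filterRows(rec, bt)
}

#' Re-reference to the average of reference channels
#'
#' Subtracts the mean of the named reference channels (e.g. the mastoids)
#' from every channel.  Re-referencing twice to the same reference equals
#' re-referencing once.
#'
#' @param rec a [ContinuousRecording-class]
#' @param referenceChannels channel labels to average
#' @return the re-referenced recording
#' @export
rereference <- function(rec, referenceChannels) {
  stopifnot(is(rec, "ContinuousRecording"))
  ix <- match(referenceChannels, rec@channels)
  if (anyNA(ix))
    stop("rereference: missing reference channel(s): ",
         paste(referenceChannels[is.na(ix)], collapse = ", "))
  ref <- colMeans(rec@data[ix, , drop = FALSE])
  rec@data <- sweep(rec@data, 2, ref)
  rec@reference <- paste0("avg(", paste(referenceChannels, collapse = ","), ")")
  rec
}

#' Decimate a recording
#'
#' Anti-aliased Fourier-domain resampling of every channel (e.g. 512 to
#' 256 Hz before band-pass filtering).
#'
#' @param rec a [ContinuousRecording-class]
#' @param fsOut target rate, Hz (must not exceed the current rate)
#' @return recording at rate fsOut
#' @export
decimateRecording <- function(rec, fsOut = 256) {
  stopifnot(is(rec, "ContinuousRecording"))
  if (fsOut > rec@fs) stop("decimateRecording: upsampling rejected")
  if (fsOut == rec@fs) return(rec)
  rec@data <- t(apply(rec@data, 1, function(ch) fftResample(ch, rec@fs, fsOut)))
  rec@fs <- fsOut
  rec
}

#' Artifact-rejection placeholder stage
#'
#' On real recordings this slot of the chain holds ICA-based artifact
#' removal and bad-channel interpolation; the package accepts already-clean
#' EEG, so the stage is a logged pass-through that keeps the chain order
#' visible.
#'
#' @param rec a [ContinuousRecording-class]
#' @param verbose emit the notice (default TRUE)
#' @return the recording, unchanged
#' @export
cleanRecording <- function(rec, verbose = TRUE) {
  if (verbose)
    message("cleanRecording: pass-through (pipeline expects already-clean EEG)")
  rec
}

#' Per-subject EEG normalization
#'
#' Each channel of each trial is centered around 0 uV, then every amplitude
#' is divided by one global (population) standard deviation computed across
#' all channels and trials, so the pooled standard deviation of the output
#' is exactly 1.
#'
#' @param recordings list of [ContinuousRecording-class] trials
#' @return list of normalized recordings
#' @export
normalizeEeg <- function(recordings) {
  if (!length(recordings)) stop("normalizeEeg: no trials")
  centered <- lapply(recordings, function(r) {
    r@data <- r@data - rowMeans(r@data)
    r
  })
  s <- .popSd(unlist(lapply(centered, function(r) as.numeric(r@data))))
  if (s == 0) stop("normalizeEeg: degenerate zero-variance pool")
  lapply(centered, function(r) { r@data <- r@data / s; r })
}
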