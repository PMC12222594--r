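# ERP stage: epoching on triggers, baseline correction, artifact rejection,
# sweep-count matching, averaging, and component amplitude/latency measures.

#' Epoch a recording around triggers
#'
#' Sweep k, channel n, sample j equals
#' \code{recording[n, trigger_k + offset_j]} with offsets spanning the
#' requested window (default -500..2000 ms).  Triggers whose window falls
#' outside the recording are dropped with a logged count.  An empty trigger
#' set yields an empty EpochSet.
#'
#' @param rec a [ContinuousRecording-class]
#' @param triggers a [TriggerSequence-class] (same sampling rate)
#' @param windowMs two-element window in ms relative to the trigger
#' @param trial trial id recorded in the provenance table
#' @return an [EpochSet-class]
#' @export
extractEpochs <- function(rec, triggers, windowMs = c(-500, 2000), trial = 1L) {
  stopifnot(is(rec, "ContinuousRecording"), is(triggers, "TriggerSequence"))
  if (rec@fs != triggers@fs) stop("extractEpochs: sampling-rate mismatch")
  offs <- .windowOffsets(windowMs, rec@fs)
  n <- ncol(rec@data)
  trig <- triggers@indices
  ok <- trig + offs[1] >= 1L & trig + offs[length(offs)] <= n
  if (any(!ok))
    message(sprintf("extractEpochs: dropped %d out-of-bounds trigger(s)", sum(!ok)))
  trig <- trig[ok]
  # vectorized gather: per channel, index a time x sweeps matrix at once
  idx <- outer(offs, trig, `+`)
  dat <- array(0, dim = c(length(offs), nrow(rec@data), length(trig)))
  if (length(trig))
    for (ch in seq_len(nrow(rec@data)))
      dat[, ch, ] <- rec@data[ch, ][idx]
  new("EpochSet", data = dat, sampleOffsets = as.integer(offs), fs = rec@fs,
      channels = rec@channels,
      provenance = data.frame(trigger = as.integer(trig),
                              trial = rep(as.integer(trial), length(trig)),
                              stream = rep(triggers@stream, length(trig))),
      accepted = rep(TRUE, length(trig)), baselined = FALSE)
}

#' Concatenate epoch sets along the sweep axis
#'
#' @param epochList list of [EpochSet-class] with identical time axes and
#'   channels
#' @return one combined [EpochSet-class]
#' @export
combineEpochs <- function(epochList) {
  epochList <- Filter(function(e) dim(e@data)[3] > 0, epochList)
  if (!length(epochList)) stop("combineEpochs: no sweeps to combine")
  e1 <- epochList[[1]]
  for (e in epochList[-1]) {
    if (!identical(e@sampleOffsets, e1@sampleOffsets) ||
        !identical(e@channels, e1@channels) || e@fs != e1@fs ||
        e@baselined != e1@baselined)
      stop("combineEpochs: incompatible epoch sets")
  }
  dat <- array(unlist(lapply(epochList, function(e) e@data)),
               dim = c(dim(e1@data)[1], dim(e1@data)[2],
                       sum(vapply(epochList, function(e) dim(e@data)[3], 0L))))
  new("EpochSet", data = dat, sampleOffsets = e1@sampleOffsets, fs = e1@fs,
      channels = e1@channels,
      provenance = do.call(rbind, lapply(epochList, function(e) e@provenance)),
      accepted = unlist(lapply(epochList, function(e) e@accepted)),
      baselined = e1@baselined)
}

#' Baseline-correct epochs
#'
#' Subtracts, per sweep and channel, the mean amplitude over the baseline
#' window (default -50..0 ms).  Applying the correction twice is a state
#' error.
#'
#' @param epochs an [EpochSet-class]
#' @param windowMs baseline window in ms, inside the epoch window
#' @return baseline-corrected [EpochSet-class]
#' @export
baselineCorrect <- function(epochs, windowMs = c(-50, 0)) {
  stopifnot(is(epochs, "EpochSet"))
  if (epochs@baselined) stop("baselineCorrect: epochs already baseline-corrected")
  offs <- .windowOffsets(windowMs, epochs@fs)
  sel <- epochs@sampleOffsets %in% offs
  if (!any(sel)) stop("baselineCorrect: baseline window outside the epoch window")
  means <- colMeans(epochs@data[sel, , , drop = FALSE]) # channels x sweeps
  epochs@data <- epochs@data -
    aperm(array(means, dim = dim(epochs@data)[c(2, 3, 1)]), c(3, 1, 2))
  epochs@baselined <- TRUE
  epochs
}

#' Reject artifact sweeps by absolute amplitude
#'
#' A sweep is rejected iff any channel at any sample exceeds the absolute
#' threshold (default 100 uV).  Expects baseline-corrected epochs.
#'
#' @param epochs a baseline-corrected [EpochSet-class]
#' @param thresholdUv positive absolute-amplitude threshold, uV
#' @return [EpochSet-class] with updated \code{accepted} mask
#' @export
rejectArtifacts <- function(epochs, thresholdUv = 100) {
  stopifnot(is(epochs, "EpochSet"))
  if (!is.finite(thresholdUv) || thresholdUv <= 0)
    stop("rejectArtifacts: threshold must be positive")
  if (!epochs@baselined)
    stop("rejectArtifacts: baseline-correct the epochs first")
  d <- dim(epochs@data)
  mx <- apply(matrix(abs(epochs@data), d[1] * d[2], d[3]), 2, max)
  epochs@accepted <- epochs@accepted & (mx <= thresholdUv)
  epochs
}

#' Match sweep counts across conditions
#'
#' Uniformly random, seed-reproducible selection of exactly n accepted
#' sweeps per condition (default: the minimum accepted count across the two
#' conditions, the data-driven analogue of a fixed per-condition quota).
#'
#' @param attended,ignored [EpochSet-class] objects
#' @param n sweeps to keep per condition (default min accepted count)
#' @param seed integer seed for the random subset
#' @return list with elements \code{attended} and \code{ignored}, each an
#'   EpochSet containing exactly n accepted sweeps
#' @export
matchSweepCounts <- function(attended, ignored, n = NULL, seed = 1) {
  nA <- sum(attended@accepted); nI <- sum(ignored@accepted)
  n <- n %||% min(nA, nI)
  if (nA < n || nI < n)
    stop(sprintf("matchSweepCounts: need %d sweeps but have %d (attended) / %d (ignored)",
                 n, nA, nI))
  set.seed(seed)
  pick <- function(e) {
    keep <- sort(sample(which(e@accepted), n))
    e@data <- e@data[, , keep, drop = FALSE]
    e@provenance <- e@provenance[keep, , drop = FALSE]
    e@accepted <- rep(TRUE, n)
    e
  }
  a <- pick(attended)
  i <- pick(ignored)
  list(attended = a, ignored = i)
}

#' Average accepted sweeps into an ERP waveform
#'
#' @param epochs an [EpochSet-class] with at least one accepted sweep
#' @return a [Waveform-class] (channels x time)
#' @export
averageErp <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  keep <- which(epochs@accepted)
  if (!length(keep)) stop("averageErp: no accepted sweeps to average")
  avg <- rowMeans(epochs@data[, , keep, drop = FALSE], dims = 2)
  new("Waveform", data = t(avg), timesMs = epochs@sampleOffsets / epochs@fs * 1000,
      fs = epochs@fs, channels = epochs@channels)
}

#' Crop a waveform to a time span
#'
#' @param wave a [Waveform-class]
#' @param spanMs two-element span in ms (default -50..500, the
#'   ERP/TRF comparison interval)
#' @return the cropped [Waveform-class]
#' @export
cropWaveform <- function(wave, spanMs = c(-50, 500)) {
  offs <- .windowOffsets(spanMs, wave@fs)
  want <- round(wave@timesMs / 1000 * wave@fs) %in% offs
  if (!any(want)) stop("cropWaveform: span outside the waveform")
  wave@data <- wave@data[, want, drop = FALSE]
  wave@timesMs <- wave@timesMs[want]
  wave
}

#' Peak latency of a component
#'
#' Latency of the extremum of the requested polarity inside the search
#' window; ties break toward the earliest sample.  A flat window returns its
#' earliest sample with a degeneracy warning.
#'
#' @param wave a [Waveform-class]
#' @param channel channel label or index
#' @param polarity "negative" (minimum) or "positive" (maximum)
#' @param searchMs two-element search window in ms
#' @return latency in ms
#' @export
peakLatency <- function(wave, channel, polarity = c("negative", "positive"),
                        searchMs) {
  polarity <- match.arg(polarity)
  ch <- if (is.character(channel)) match(channel, wave@channels) else channel
  if (is.na(ch)) stop("peakLatency: unknown channel")
  sel <- wave@timesMs >= searchMs[1] & wave@timesMs <= searchMs[2]
  if (!any(sel)) stop("peakLatency: empty search window")
  y <- wave@data[ch, sel]
  if (diff(range(y)) == 0)
    warning("peakLatency: flat waveform in search window; returning earliest sample")
  ix <- if (polarity == "negative") which.min(y) else which.max(y)
  wave@timesMs[sel][ix]
}

#' Mean component amplitude in a latency window
#'
#' Mean voltage over samples with \code{center - halfWidth <= t <= center +
#' halfWidth} (default half-width 20 ms).
#'
#' @param wave a [Waveform-class]
#' @param channel channel label or index
#' @param centerMs window center, ms
#' @param halfWidthMs window half-width, ms
#' @return mean amplitude in uV
#' @export
componentAmplitude <- function(wave, channel, centerMs, halfWidthMs = 20) {
  ch <- if (is.character(channel)) match(channel, wave@channels) else channel
  if (is.na(ch)) stop("componentAmplitude: unknown channel")
  sel <- wave@timesMs >= centerMs - halfWidthMs & wave@timesMs <= centerMs + halfWidthMs
  if (!any(sel)) stop("componentAmplitude: window outside the waveform span")
  mean(wave@data[ch, sel])
}

#' N1-P2 peak-to-peak amplitude
#'
#' P2 minus N1 windowed mean amplitudes with shared half-width.
#'
#' @param wave a [Waveform-class]
#' @param channel channel label or index
#' @param n1CenterMs,p2CenterMs window centers from the attended-condition
#'   grand average
#' @param halfWidthMs window half-width (default 20 ms)
#' @return N1-P2 amplitude in uV
#' @export
n1p2Amplitude <- function(wave, channel, n1CenterMs, p2CenterMs, halfWidthMs = 20) {
  componentAmplitude(wave, channel, p2CenterMs, halfWidthMs) -
    componentAmplitude(wave, channel, n1CenterMs, halfWidthMs)
}
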