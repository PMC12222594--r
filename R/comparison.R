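# ERP-TRF similarity: cross-correlation lag, spatial (topographic)
# correlation time courses, per-channel waveform correlation.

.waveMat <- function(x) if (is(x, "Waveform")) x@data else as.matrix(x)

#' Best-fit lag between two waveforms
#'
#' The integer lag maximizing the normalized cross-correlation between the
#' two waveforms at the designated channel; a positive lag means the second
#' waveform precedes the first by that many samples.  With per-participant
#' waveform lists the participant-mean correlation is maximized.  Ties break
#' toward the smaller absolute lag.
#'
#' @param reference,other [Waveform-class] objects (or numeric vectors), or
#'   lists of them (one per participant)
#' @param channel channel label/index used for the cross-correlation
#'   (ignored for vector input)
#' @param maxLag maximum absolute lag in samples (default 32); must be
#'   smaller than the overlapping span
#' @return best-fit lag in samples
#' @export
bestLag <- function(reference, other, channel = 1, maxLag = 32) {
  asVec <- function(w) {
    if (is.numeric(w) && is.null(dim(w))) return(as.numeric(w))
    m <- .waveMat(w)
    ch <- if (is.character(channel)) match(channel, w@channels) else channel
    m[ch, ]
  }
  refs <- if (is.list(reference)) lapply(reference, asVec) else list(asVec(reference))
  oths <- if (is.list(other)) lapply(other, asVec) else list(asVec(other))
  n <- length(refs[[1]])
  if (maxLag >= n) stop("bestLag: maxLag must be smaller than the waveform span")
  lags <- -maxLag:maxLag
  score <- vapply(lags, function(l) {
    mean(mapply(function(a, b) {
      # shift b by +l samples and correlate over the overlap
      ia <- max(1, 1 + l):min(n, n + l)
      ib <- ia - l
      if (stats::sd(a[ia]) == 0 || stats::sd(b[ib]) == 0) return(-Inf)
      stats::cor(a[ia], b[ib])
    }, refs, oths))
  }, 0)
  best <- which(score == max(score))
  lags[best[which.min(abs(lags[best]))]]
}

#' Shift a waveform by an integer number of samples
#'
#' Positive lags move the waveform later in time (edge samples are dropped
#' on one side and the span is cropped accordingly on the other), aligning a
#' leading TRF with its ERP.
#'
#' @param wave a [Waveform-class]
#' @param lag integer shift in samples
#' @return the shifted, cropped [Waveform-class]
#' @export
shiftWaveform <- function(wave, lag) {
  if (lag == 0) return(wave)
  n <- ncol(wave@data)
  if (abs(lag) >= n) stop("shiftWaveform: lag exceeds the waveform span")
  if (lag > 0) {
    wave@data <- wave@data[, 1:(n - lag), drop = FALSE]
    wave@timesMs <- wave@timesMs[(lag + 1):n]
  } else {
    wave@data <- wave@data[, (1 - lag):n, drop = FALSE]
    wave@timesMs <- wave@timesMs[1:(n + lag)]
  }
  wave
}

#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of two single-latency topography
#' frames; 1 for identical, -1 for perfectly inverted maps.  Needs at least
#' 3 channels and nonzero variance in both frames.
#'
#' @param a,b numeric per-channel vectors (same channel order)
#' @return the spatial correlation r2D
#' @export
spatialCorrelation <- function(a, b) {
  if (length(a) != length(b)) stop("spatialCorrelation: channel sets differ")
  if (length(a) < 3) stop("spatialCorrelation: need at least 3 channels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("spatialCorrelation: zero-variance frame, correlation undefined")
  stats::cor(a, b)
}

#' Sample-wise topographic similarity time course
#'
#' One spatial correlation per time sample between an ERP and a
#' lag-corrected TRF waveform over a common span (default -50..500 ms).
#'
#' @param erp,trf [Waveform-class] objects with identical channels; the TRF
#'   should already be lag-corrected
#' @param spanMs analysis span in ms
#' @return numeric vector of r2D values with attribute \code{timesMs}
#' @export
topographicSimilarityCourse <- function(erp, trf, spanMs = c(-50, 500)) {
  if (!identical(erp@channels, trf@channels))
    stop("topographicSimilarityCourse: channel sets differ")
  tt <- intersect(round(erp@timesMs[erp@timesMs >= spanMs[1] & erp@timesMs <= spanMs[2]], 6),
                  round(trf@timesMs, 6))
  if (!length(tt)) stop("topographicSimilarityCourse: span outside the waveforms")
  ia <- match(tt, round(erp@timesMs, 6))
  ib <- match(tt, round(trf@timesMs, 6))
  r <- vapply(seq_along(tt), function(j)
    spatialCorrelation(erp@data[, ia[j]], trf@data[, ib[j]]), 0)
  structure(r, timesMs = tt)
}

#' Per-channel waveform correlation
#'
#' Pearson correlation along time, per channel, between an ERP and a
#' lag-corrected TRF over a common span.
#'
#' @param erp,trf [Waveform-class] objects with identical channels
#' @param spanMs analysis span in ms
#' @return named numeric vector, one r per channel
#' @export
waveformCorrelationPerChannel <- function(erp, trf, spanMs = c(-50, 500)) {
  if (!identical(erp@channels, trf@channels))
    stop("waveformCorrelationPerChannel: channel sets differ")
  tt <- intersect(round(erp@timesMs[erp@timesMs >= spanMs[1] & erp@timesMs <= spanMs[2]], 6),
                  round(trf@timesMs, 6))
  if (!length(tt)) stop("waveformCorrelationPerChannel: span outside the waveforms")
  ia <- match(tt, round(erp@timesMs, 6))
  ib <- match(tt, round(trf@timesMs, 6))
  r <- vapply(seq_len(nrow(erp@data)), function(ch)
    stats::cor(erp@data[ch, ia], trf@data[ch, ib]), 0)
  names(r) <- erp@channels
  r
}
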