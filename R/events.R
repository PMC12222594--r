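# Trigger extraction: pooled 2-sigma threshold rule on onset envelopes.

#' Pooled standard deviation of an envelope pool
#'
#' Population standard deviation (divide by N) over the concatenation of all
#' samples of all provided envelopes.  In the standard chain the pool holds
#' one subject's 40 envelopes (2 streams x 20 trials).
#'
#' @param envelopes list of numeric vectors or [OnsetEnvelope-class] objects
#'   (a single object is also accepted)
#' @return sigma_env, the pooled population standard deviation
#' @examples
#' pooledSigma(list(c(0, 0, 0, 4))) # sqrt(3)
#' @export
pooledSigma <- function(envelopes) {
  if (is(envelopes, "OnsetEnvelope") || is.numeric(envelopes))
    envelopes <- list(envelopes)
  if (!length(envelopes)) stop("pooledSigma: empty pool")
  vals <- unlist(lapply(envelopes, function(e)
    if (is(e, "OnsetEnvelope")) e@values else e))
  if (!length(vals)) stop("pooledSigma: empty pool")
  .popSd(vals)
}

#' Extract segmentation triggers from an onset envelope
#'
#' A trigger is inserted at every sample i >= 2 at which the envelope changes
#' from sub- to suprathreshold amplitude
#' (\code{env[i-1] <= threshold & env[i] > threshold}).  The very first
#' sample can never be a trigger since it has no defined predecessor.
#'
#' @param env an [OnsetEnvelope-class] or numeric vector
#' @param threshold amplitude threshold, conventionally \code{2 * sigma_env};
#'   must be > 0
#' @param fs sampling rate when \code{env} is a plain vector
#' @param stream stream label carried into the result
#' @return a [TriggerSequence-class]
#' @export
extractTriggers <- function(env, threshold, fs = NULL, stream = "unknown") {
  if (is(env, "OnsetEnvelope")) {
    fs <- env@fs
    x <- env@values
  } else x <- env
  if (is.null(fs)) stop("fs required for plain numeric input")
  if (!is.finite(threshold) || threshold <= 0)
    stop("extractTriggers: threshold must be a positive finite number")
  n <- length(x)
  idx <- if (n >= 2) which(x[-1] > threshold & x[-n] <= threshold) + 1L else integer(0)
  new("TriggerSequence", indices = as.integer(idx), fs = fs,
      threshold = threshold, stream = stream)
}

#' @rdname trimEdges
setMethod("trimEdges", "ContinuousRecording", function(x, seconds = 1, length = NULL) {
  nTrim <- round(seconds * x@fs)
  n <- ncol(x@data)
  if (n <= 2 * nTrim) stop("trimEdges: recording shorter than twice the trim span")
  if (nTrim == 0) return(x)
  x@data <- x@data[, (nTrim + 1):(n - nTrim), drop = FALSE]
  x
})

#' @rdname trimEdges
setMethod("trimEdges", "OnsetEnvelope", function(x, seconds = 1, length = NULL) {
  nTrim <- round(seconds * x@fs)
  n <- base::length(x@values)
  if (n <= 2 * nTrim) stop("trimEdges: envelope shorter than twice the trim span")
  if (nTrim == 0) return(x)
  x@values <- x@values[(nTrim + 1):(n - nTrim)]
  x
})

#' @rdname trimEdges
setMethod("trimEdges", "TriggerSequence", function(x, seconds = 1, length = NULL) {
  if (is.null(length)) stop("trimEdges: original series length required for triggers")
  nTrim <- round(seconds * x@fs)
  keep <- x@indices > nTrim & x@indices <= (length - nTrim)
  x@indices <- x@indices[keep] - as.integer(nTrim)
  x
})
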