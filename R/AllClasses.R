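# S4 containers for the pipeline.  Conventions: channel x time matrices,
# sampling rates in Hz, latencies in ms, amplitudes in microvolts.

#' KernelSpec: parametric P1-N1-P2 response kernel
#'
#' A sum of signed Gaussian components describing a stereotypical evoked
#' response.  Each row of \code{components} holds \code{polarity} (+1/-1),
#' \code{latencyMs} (peak latency), \code{sigmaMs} (Gaussian width) and
#' \code{amplitudeUv} (positive magnitude, microvolts).
#'
#' @slot components data.frame with columns polarity, latencyMs, sigmaMs,
#'   amplitudeUv; latencies strictly increasing.
#' @slot durationMs total kernel duration in ms.
#' @exportClass KernelSpec
setClass("KernelSpec",
  slots = c(components = "data.frame", durationMs = "numeric"))

setValidity("KernelSpec", function(object) {
  cmp <- object@components
  need <- c("polarity", "latencyMs", "sigmaMs", "amplitudeUv")
  if (!all(need %in% names(cmp)))
    return(sprintf("components must have columns %s", paste(need, collapse = ", ")))
  if (nrow(cmp)) {
    if (any(diff(cmp$latencyMs) <= 0)) return("peak latencies must be strictly increasing")
    if (any(cmp$sigmaMs <= 0)) return("component widths must be > 0")
    if (!all(cmp$polarity %in% c(-1, 1))) return("polarity must be +1 or -1")
    if (any(cmp$amplitudeUv < 0)) return("amplitudes are magnitudes and must be >= 0")
    # kernel must be negligible at the t = 0 boundary (< 1% of max amplitude)
    edge <- sum(cmp$amplitudeUv * exp(-(cmp$latencyMs)^2 / (2 * cmp$sigmaMs^2)))
    if (edge > 0.01 * max(cmp$amplitudeUv))
      return("kernel does not decay to ~0 at t = 0 (component too close to onset)")
  }
  if (length(object@durationMs) != 1L || object@durationMs <= 0)
    return("durationMs must be a positive scalar")
  TRUE
})

#' CohortSpec: design of a synthetic cocktail-party cohort
#'
#' Holds every knob of the generator: cohort geometry, pulse-train process,
#' attention gain, channel topography, 1/f noise shape and the master seed.
#'
#' @slot nSubjects,nTrials,nChannels counts (>= 1).
#' @slot trialDurationS trial duration, seconds.
#' @slot fsEeg EEG sampling rate, Hz.
#' @slot pulseRate mean acoustic-edge rate, events/s.
#' @slot pulseWidthSigmaMs Gaussian pulse width, ms.
#' @slot amplitudeLaw named numeric c(meanlog=, sdlog=) of the log-normal
#'   pulse-height law.
#' @slot attentionGainN1 multiplier applied to the N1 amplitude of the
#'   ignored-stream kernel (1 = no attention effect).
#' @slot topography per-channel gain vector (unit norm by convention).
#' @slot noiseExponent 1/f^a spectral exponent of the additive noise.
#' @slot snrDb per-trial evoked-signal-to-noise ratio, dB.
#' @slot spatiallyCorrelatedNoise logical; mix noise across channels.
#' @slot seed integer master seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  slots = c(nSubjects = "integer", nTrials = "integer", trialDurationS = "numeric",
            fsEeg = "numeric", nChannels = "integer", pulseRate = "numeric",
            pulseWidthSigmaMs = "numeric", amplitudeLaw = "numeric",
            attentionGainN1 = "numeric", topography = "numeric",
            noiseExponent = "numeric", snrDb = "numeric",
            spatiallyCorrelatedNoise = "logical", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nSubjects < 1L || object@nTrials < 1L || object@nChannels < 1L)
    return("all counts must be >= 1")
  if (object@trialDurationS <= 0 || object@fsEeg <= 0) return("duration and fs must be positive")
  if (!all(is.finite(c(object@pulseRate, object@pulseWidthSigmaMs, object@amplitudeLaw,
                       object@attentionGainN1, object@noiseExponent, object@snrDb))))
    return("all numeric parameters must be finite")
  if (object@pulseRate < 0) return("pulseRate must be >= 0")
  if (object@trialDurationS * object@pulseRate < 10)
    return("trialDurationS * pulseRate must be >= 10 so trigger statistics are estimable")
  if (length(object@topography) != object@nChannels)
    return("topography must have one entry per channel")
  if (!all(c("meanlog", "sdlog") %in% names(object@amplitudeLaw)))
    return("amplitudeLaw needs named entries meanlog, sdlog")
  TRUE
})

#' GroundTruth: generative record of one simulated subject
#'
#' @slot attendedKernel,ignoredKernel the [KernelSpec]s convolved with the two
#'   pulse trains.
#' @slot pulses data.frame (trial, stream, timeS, sample, amplitude) of every
#'   generated pulse; times strictly increasing within trial and stream.
#' @slot topography per-channel projection gains.
#' @slot seed the per-subject seed actually used.
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(attendedKernel = "KernelSpec", ignoredKernel = "KernelSpec",
            pulses = "data.frame", topography = "numeric", seed = "integer"))

setValidity("GroundTruth", function(object) {
  p <- object@pulses
  if (nrow(p)) {
    ok <- vapply(split(p$timeS, interaction(p$trial, p$stream, drop = TRUE)),
                 function(v) all(diff(v) > 0), logical(1))
    if (!all(ok)) return("pulse times must be strictly increasing within trial and stream")
  }
  TRUE
})

#' ContinuousRecording: multichannel time series
#'
#' Channels x samples matrix with sampling rate, labels and reference state;
#' the response r(t, n) of the forward model.
#'
#' @slot data channels x samples numeric matrix (microvolts for EEG).
#' @slot fs sampling rate, Hz.
#' @slot channels channel labels, one per row.
#' @slot reference free-text reference state (e.g. "raw", "avg(M1,M2)").
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  slots = c(data = "matrix", fs = "numeric", channels = "character",
            reference = "character"))

setValidity("ContinuousRecording", function(object) {
  if (anyNA(object@data)) return("recording must not contain NA")
  if (length(object@channels) != nrow(object@data))
    return("one channel label per data row required")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a positive scalar")
  TRUE
})

#' OnsetEnvelope: single-channel nonnegative onset-envelope series
#'
#' @slot values nonnegative samples.
#' @slot fs sampling rate, Hz.
#' @slot sourceId free-text provenance label.
#' @slot pooledSigma the pooled standard deviation (sigma_env) once set by
#'   [pooledSigma()]; NA before pooling.
#' @slot pulses data.frame of generative pulse times/amplitudes when the
#'   envelope was simulated (empty for audio-derived envelopes).
#' @exportClass OnsetEnvelope
setClass("OnsetEnvelope",
  slots = c(values = "numeric", fs = "numeric", sourceId = "character",
            pooledSigma = "numeric", pulses = "data.frame"))

setValidity("OnsetEnvelope", function(object) {
  if (length(object@values) && min(object@values) < 0)
    return("onset envelope must be nonnegative")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a positive scalar")
  TRUE
})

#' TriggerSequence: segmentation markers from an onset envelope
#'
#' @slot indices strictly increasing 1-based sample indices of sub- to
#'   supra-threshold crossings.
#' @slot fs sampling rate, Hz.
#' @slot threshold amplitude threshold used (2 * sigma_env).
#' @slot stream source stream label ("attended"/"ignored"/other).
#' @exportClass TriggerSequence
setClass("TriggerSequence",
  slots = c(indices = "integer", fs = "numeric", threshold = "numeric",
            stream = "character"))

setValidity("TriggerSequence", function(object) {
  if (length(object@indices) && any(diff(object@indices) <= 0))
    return("trigger indices must be strictly increasing")
  if (length(object@indices) && object@indices[1] < 1L)
    return("trigger indices must be >= 1")
  TRUE
})

#' EpochSet: single-sweep epochs around triggers
#'
#' Data are stored time x channels x sweeps; the time axis is
#' \code{sampleOffsets / fs} relative to the trigger.
#'
#' @slot data time x channels x sweeps array, microvolts.
#' @slot sampleOffsets integer sample offsets (e.g. -128..512 for a
#'   -500..2000 ms window at 256 Hz).
#' @slot fs sampling rate, Hz.
#' @slot channels channel labels.
#' @slot provenance data.frame (trigger, trial, stream) per sweep.
#' @slot accepted logical per sweep; FALSE marks rejected artifacts.
#' @slot baselined logical flag, TRUE once baseline-corrected.
#' @exportClass EpochSet
setClass("EpochSet",
  slots = c(data = "array", sampleOffsets = "integer", fs = "numeric",
            channels = "character", provenance = "data.frame",
            accepted = "logical", baselined = "logical"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array (time x channels x sweeps)")
  if (d[1] != length(object@sampleOffsets)) return("time axis/sampleOffsets mismatch")
  if (d[2] != length(object@channels)) return("channel axis/labels mismatch")
  if (d[3] != length(object@accepted)) return("sweep axis/accepted mask mismatch")
  if (nrow(object@provenance) != d[3]) return("provenance must have one row per sweep")
  TRUE
})

#' Waveform: averaged response (ERP or postprocessed TRF)
#'
#' @slot data channels x time matrix, microvolts.
#' @slot timesMs time (or lag) axis in ms.
#' @slot fs sampling rate, Hz.
#' @slot channels channel labels.
#' @exportClass Waveform
setClass("Waveform",
  slots = c(data = "matrix", timesMs = "numeric", fs = "numeric",
            channels = "character"))

setValidity("Waveform", function(object) {
  if (ncol(object@data) != length(object@timesMs)) return("time axis mismatch")
  if (nrow(object@data) != length(object@channels)) return("channel axis mismatch")
  TRUE
})

#' MorseFamily: analytic generalized Morse wavelet bank
#'
#' @slot gamma,beta shape parameters (defaults 3 and 3.29).
#' @slot freqsHz strictly increasing peak ("center") frequencies, Hz.
#' @slot fs sampling rate of the signals to transform, Hz.
#' @exportClass MorseFamily
setClass("MorseFamily",
  slots = c(gamma = "numeric", beta = "numeric", freqsHz = "numeric",
            fs = "numeric"))

setValidity("MorseFamily", function(object) {
  if (object@gamma <= 0 || object@beta <= 0) return("gamma and beta must be > 0")
  if (any(diff(object@freqsHz) <= 0)) return("frequency grid must be strictly increasing")
  if (max(object@freqsHz) >= object@fs / 2) return("center frequencies must be < fs/2")
  TRUE
})

#' WpssMap: wavelet phase synchronization stability map
#'
#' @slot values frequencies x time matrix in [0, 1].
#' @slot freqsHz frequency axis, Hz.
#' @slot timesMs time axis, ms relative to trigger.
#' @slot nSweeps number of sweeps entering the resultant (>= 2).
#' @slot channel,condition provenance labels.
#' @exportClass WpssMap
setClass("WpssMap",
  slots = c(values = "matrix", freqsHz = "numeric", timesMs = "numeric",
            nSweeps = "integer", channel = "character", condition = "character"))

setValidity("WpssMap", function(object) {
  v <- object@values
  if (nrow(v) != length(object@freqsHz) || ncol(v) != length(object@timesMs))
    return("axis/metadata mismatch")
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    return("WPSS values must lie in [0, 1]")
  if (object@nSweeps < 2L) return("WPSS is undefined for fewer than 2 sweeps")
  TRUE
})

#' LagGrid: integer lag grid of a linear model
#'
#' @slot tauMinMs,tauMaxMs lag range, ms.
#' @slot fs sampling rate, Hz.
#' @slot lags consecutive integer sample lags round(tauMin*fs)..round(tauMax*fs).
#' @exportClass LagGrid
setClass("LagGrid",
  slots = c(tauMinMs = "numeric", tauMaxMs = "numeric", fs = "numeric",
            lags = "integer"))

setValidity("LagGrid", function(object) {
  expect <- seq.int(round(object@tauMinMs / 1000 * object@fs),
                    round(object@tauMaxMs / 1000 * object@fs))
  if (!identical(as.integer(expect), object@lags))
    return("lags must be the consecutive integers round(tauMin*fs)..round(tauMax*fs)")
  TRUE
})

#' LinearModel: forward TRF or backward stimulus-reconstruction decoder
#'
#' Weights are stored lags x channels for both directions: column n of a
#' backward model holds g(tau, n), the block of the stacked decoder
#' corresponding to channel n.
#'
#' @slot direction "forward" or "backward".
#' @slot weights lags x channels matrix.
#' @slot lagGrid the [LagGrid] used.
#' @slot lambdas regularization values, recorded verbatim.
#' @slot channels channel labels (targets for forward, sources for backward).
#' @slot trials training trial ids.
#' @slot postprocessed logical flag for forward models.
#' @exportClass LinearModel
setClass("LinearModel",
  slots = c(direction = "character", weights = "matrix", lagGrid = "LagGrid",
            lambdas = "numeric", channels = "character", trials = "integer",
            postprocessed = "logical"))

setValidity("LinearModel", function(object) {
  if (!object@direction %in% c("forward", "backward"))
    return("direction must be 'forward' or 'backward'")
  if (nrow(object@weights) != length(object@lagGrid@lags))
    return("weight rows must match the lag grid")
  if (ncol(object@weights) != length(object@channels))
    return("weight columns must match the channel labels")
  TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording: %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs, object@reference))
})

setMethod("show", "OnsetEnvelope", function(object) {
  cat(sprintf("OnsetEnvelope '%s': %d samples @ %g Hz, pooled sigma %s\n",
              object@sourceId, length(object@values), object@fs,
              ifelse(is.na(object@pooledSigma), "<unset>",
                     format(object@pooledSigma, digits = 4))))
})

setMethod("show", "TriggerSequence", function(object) {
  cat(sprintf("TriggerSequence (%s): %d triggers @ %g Hz, threshold %.4g\n",
              object@stream, length(object@indices), object@fs, object@threshold))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d sweeps x %d channels x %d samples @ %g Hz (%d accepted%s)\n",
              d[3], d[2], d[1], object@fs, sum(object@accepted),
              ifelse(object@baselined, ", baselined", "")))
})

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d channels, %.1f..%.1f ms @ %g Hz\n",
              nrow(object@data), min(object@timesMs), max(object@timesMs), object@fs))
})

setMethod("show", "MorseFamily", function(object) {
  cat(sprintf("MorseFamily psi_(%g, %g): %d scales, %.3g..%.3g Hz @ %g Hz\n",
              object@gamma, object@beta, length(object@freqsHz),
              min(object@freqsHz), max(object@freqsHz), object@fs))
})

setMethod("show", "WpssMap", function(object) {
  cat(sprintf("WpssMap [%s/%s]: %d freqs x %d times, %d sweeps, range %.3f..%.3f\n",
              object@channel, object@condition, nrow(object@values),
              ncol(object@values), object@nSweeps,
              min(object@values), max(object@values)))
})

setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel (%s): %d lags (%g..%g ms) x %d channels, %d lambdas%s\n",
              object@direction, nrow(object@weights), object@lagGrid@tauMinMs,
              object@lagGrid@tauMaxMs, ncol(object@weights),
              length(object@lambdas),
              ifelse(object@postprocessed, ", postprocessed", "")))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d subjects x %d trials x %g s, %d channels @ %g Hz\n",
                     "  pulses %g/s (sigma %g ms), N1 gain %g, SNR %g dB, seed %d\n"),
              object@nSubjects, object@nTrials, object@trialDurationS,
              object@nChannels, object@fsEeg, object@pulseRate,
              object@pulseWidthSigmaMs, object@attentionGainN1, object@snrDb,
              object@seed))
})
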