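# Synthetic cocktail-party cohort generator.
#
# Each simulated trial superimposes the responses evoked by two concurrent
# streams of acoustic edges: a Gaussian pulse train per stream is convolved
# with a P1-N1-P2 kernel (the N1 of the ignored stream is attenuated by the
# attention gain), projected through a frontocentral channel topography, and
# buried in 1/f noise at a configurable per-trial SNR.

#' Construct a KernelSpec
#'
#' @param components data.frame with columns \code{polarity} (+1/-1),
#'   \code{latencyMs}, \code{sigmaMs}, \code{amplitudeUv}.
#' @param durationMs kernel duration in ms (default 600).
#' @return a [KernelSpec-class] object
#' @examples
#' kernelSpec(data.frame(polarity = c(1, -1, 1), latencyMs = c(80, 135, 225),
#'                       sigmaMs = c(15, 22, 30), amplitudeUv = c(0.5, 1, 0.8)))
#' @export
kernelSpec <- function(components, durationMs = 600) {
  new("KernelSpec", components = components, durationMs = durationMs)
}

#' Default attended-stream P1-N1-P2 kernel
#'
#' P1 +0.5 uV at 80 ms (sigma 15 ms), N1 -1.0 uV at 135 ms (sigma 22 ms),
#' P2 +0.8 uV at 225 ms (sigma 30 ms).
#' @return a [KernelSpec-class]
#' @export
defaultAttendedKernel <- function() {
  kernelSpec(data.frame(polarity = c(1, -1, 1),
                        latencyMs = c(80, 135, 225),
                        sigmaMs = c(15, 22, 30),
                        amplitudeUv = c(0.5, 1.0, 0.8)))
}

#' Ignored-stream kernel: attended kernel with attenuated N1
#'
#' @param attended the attended-stream [KernelSpec-class]
#' @param gainN1 multiplier on the N1 (most negative component) amplitude;
#'   \code{gainN1 = 1} reproduces the attended kernel exactly.
#' @return a [KernelSpec-class]
#' @export
ignoredKernel <- function(attended = defaultAttendedKernel(), gainN1 = 0.4) {
  cmp <- attended@components
  neg <- which(cmp$polarity < 0)
  if (length(neg)) {
    n1 <- neg[which.max(cmp$amplitudeUv[neg])]
    cmp$amplitudeUv[n1] <- cmp$amplitudeUv[n1] * gainN1
  }
  kernelSpec(cmp, attended@durationMs)
}

#' Sample a kernel on a time grid
#'
#' Evaluates the sum of signed Gaussians on \code{t = 0, 1/fs, ...} up to the
#' kernel duration.
#'
#' @param spec a [KernelSpec-class]
#' @param fs sampling rate, Hz
#' @return numeric vector of length \code{round(durationMs/1000 * fs)} with
#'   attribute \code{timesMs}
#' @export
renderKernel <- function(spec, fs) {
  stopifnot(is(spec, "KernelSpec"), fs > 0)
  n <- round(spec@durationMs / 1000 * fs)
  tMs <- (seq_len(n) - 1) / fs * 1000
  k <- numeric(n)
  cmp <- spec@components
  for (i in seq_len(nrow(cmp)))
    k <- k + cmp$polarity[i] * cmp$amplitudeUv[i] *
      exp(-(tMs - cmp$latencyMs[i])^2 / (2 * cmp$sigmaMs[i]^2))
  structure(k, timesMs = tMs)
}

#' Construct a CohortSpec
#'
#' Defaults mirror the structure of a two-speaker selective-attention EEG
#' study (20 trials of 50 s per subject at 256 Hz) at a desk-scale channel
#' count, with pulse statistics calibrated so that roughly 2.7 edges per
#' second clear the pooled 2-sigma trigger threshold.
#'
#' @param nSubjects,nTrials,nChannels cohort geometry
#' @param trialDurationS trial duration in seconds
#' @param fsEeg sampling rate in Hz
#' @param pulseRate mean edge rate, events/s
#' @param pulseWidthSigmaMs Gaussian pulse width, ms
#' @param amplitudeLaw named numeric \code{c(meanlog=, sdlog=)}
#' @param attentionGainN1 N1 multiplier for the ignored kernel
#' @param topography per-channel gains (default [defaultTopography()])
#' @param noiseExponent 1/f^a noise exponent
#' @param snrDb per-trial evoked/noise power ratio in dB
#' @param spatiallyCorrelatedNoise mix noise across channels
#' @param seed integer master seed
#' @return a [CohortSpec-class]
#' @export
cohortSpec <- function(nSubjects = 12, nTrials = 20, trialDurationS = 50,
                       fsEeg = 256, nChannels = 16, pulseRate = 3.4,
                       pulseWidthSigmaMs = 5,
                       amplitudeLaw = c(meanlog = 0, sdlog = 0.7),
                       attentionGainN1 = 0.4,
                       topography = defaultTopography(nChannels),
                       noiseExponent = 1, snrDb = -10,
                       spatiallyCorrelatedNoise = FALSE, seed = 1) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      nTrials = as.integer(nTrials), trialDurationS = trialDurationS,
      fsEeg = fsEeg, nChannels = as.integer(nChannels), pulseRate = pulseRate,
      pulseWidthSigmaMs = pulseWidthSigmaMs, amplitudeLaw = amplitudeLaw,
      attentionGainN1 = attentionGainN1, topography = topography,
      noiseExponent = noiseExponent, snrDb = snrDb,
      spatiallyCorrelatedNoise = spatiallyCorrelatedNoise,
      seed = as.integer(seed))
}

#' Frontocentral channel topography
#'
#' Unit-norm gain vector with its maximum at a designated "Cz-like" channel
#' and Gaussian decay with nominal scalp distance.
#'
#' @param nChannels number of channels
#' @param peak index of the peak channel (default: middle channel)
#' @param spread Gaussian spread of the decay in channel units
#'   (default nChannels/5)
#' @return numeric vector of unit Euclidean norm
#' @export
defaultTopography <- function(nChannels, peak = ceiling(nChannels / 2),
                              spread = nChannels / 5) {
  g <- exp(-((seq_len(nChannels) - peak)^2) / (2 * spread^2))
  g / sqrt(sum(g^2))
}

#' Channel labels for a synthetic montage
#'
#' Generic labels E01, E02, ... with the topography peak named "Cz".
#' @param nChannels number of channels
#' @param peak peak channel index
#' @return character vector
#' @export
syntheticChannelNames <- function(nChannels, peak = ceiling(nChannels / 2)) {
  lab <- sprintf("E%02d", seq_len(nChannels))
  lab[peak] <- "Cz"
  lab
}

#' Simulate an onset-envelope pulse train
#'
#' Inter-onset intervals are gamma-distributed (shape 2, mean \code{1/rate})
#' and pulse heights follow a log-normal law, so that a pooled 2-sigma
#' threshold passes only a subset of pulses, as for real speech onset
#' envelopes.
#'
#' @param durationS duration in seconds
#' @param fs sampling rate, Hz
#' @param rate mean pulse rate, events/s; \code{rate = 0} yields a flat zero
#'   envelope
#' @param widthSigmaMs Gaussian pulse width, ms
#' @param amplitudeLaw named numeric \code{c(meanlog=, sdlog=)}
#' @param seed optional integer seed; when NULL the current RNG state is used
#' @param sourceId provenance label
#' @return an [OnsetEnvelope-class] whose \code{pulses} slot records the
#'   generated pulse times and amplitudes
#' @export
simulatePulseTrain <- function(durationS, fs, rate, widthSigmaMs = 5,
                               amplitudeLaw = c(meanlog = 0, sdlog = 0.7),
                               seed = NULL, sourceId = "simulated") {
  if (!all(is.finite(c(durationS, fs, rate, widthSigmaMs, amplitudeLaw))))
    stop("simulatePulseTrain: parameters must be finite")
  if (durationS <= 0 || fs <= 0 || rate < 0)
    stop("simulatePulseTrain: durationS and fs must be positive, rate >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(durationS * fs)
  vals <- numeric(n)
  pulses <- data.frame(timeS = numeric(0), amplitude = numeric(0))
  if (rate > 0) {
    # draw more intervals than needed, then truncate to the trial
    nDraw <- max(20L, ceiling(durationS * rate * 2 + 10 * sqrt(durationS * rate)))
    t0 <- cumsum(stats::rgamma(nDraw, shape = 2, scale = 1 / (2 * rate)))
    while (length(t0) && t0[length(t0)] < durationS) {
      extra <- cumsum(stats::rgamma(nDraw, shape = 2, scale = 1 / (2 * rate)))
      t0 <- c(t0, t0[length(t0)] + extra)
    }
    t0 <- t0[t0 < durationS]
    amp <- stats::rlnorm(length(t0), meanlog = amplitudeLaw[["meanlog"]],
                         sdlog = amplitudeLaw[["sdlog"]])
    sw <- widthSigmaMs / 1000
    halo <- ceiling(5 * sw * fs)
    grid <- (seq_len(n) - 1) / fs
    for (i in seq_along(t0)) {
      c0 <- round(t0[i] * fs) + 1
      idx <- max(1L, c0 - halo):min(n, c0 + halo)
      vals[idx] <- vals[idx] + amp[i] * exp(-(grid[idx] - t0[i])^2 / (2 * sw^2))
    }
    pulses <- data.frame(timeS = t0, amplitude = amp)
  }
  new("OnsetEnvelope", values = vals, fs = fs, sourceId = sourceId,
      pooledSigma = NA_real_, pulses = pulses)
}

# spectrally shaped (1/f^a power) Gaussian noise, unit variance
.oneOverFNoise <- function(n, exponent, fs) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  X <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n # two-sided frequency magnitude
  g <- c(0, f[-1]^(-exponent / 2)) # kill DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / .popSd(y)
}

#' Simulate one subject of a cocktail-party cohort
#'
#' Per trial, the EEG at channel n is
#' \code{topography[n] * (attended_train * attended_kernel +
#' ignored_train * ignored_kernel)} (discrete convolutions) plus 1/f noise
#' scaled to the requested per-trial SNR.  All randomness derives from the
#' cohort seed and the subject index, so identical specs give bit-identical
#' cohorts.
#'
#' @param spec a [CohortSpec-class]
#' @param subjectIndex 1-based subject index
#' @return list with elements \code{eeg} (list of [ContinuousRecording-class]
#'   per trial), \code{envelopes} (per trial, a list with members
#'   \code{attended} and \code{ignored} [OnsetEnvelope-class]), and
#'   \code{truth} (a [GroundTruth-class])
#' @export
simulateSubject <- function(spec, subjectIndex) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  if (length(spec@topography) != spec@nChannels)
    stop("topography/channel count mismatch")
  fs <- spec@fsEeg
  n <- round(spec@trialDurationS * fs)
  kAtt <- defaultAttendedKernel()
  kIgn <- ignoredKernel(kAtt, spec@attentionGainN1)
  hAtt <- renderKernel(kAtt, fs)
  hIgn <- renderKernel(kIgn, fs)
  chan <- syntheticChannelNames(spec@nChannels, which.max(spec@topography))
  eeg <- vector("list", spec@nTrials)
  envs <- vector("list", spec@nTrials)
  pulseLog <- list()
  for (tr in seq_len(spec@nTrials)) {
    envA <- simulatePulseTrain(spec@trialDurationS, fs, spec@pulseRate,
                               spec@pulseWidthSigmaMs, spec@amplitudeLaw,
                               seed = .subSeed(spec@seed, subjectIndex, tr, 1L),
                               sourceId = sprintf("s%02d_t%02d_att", subjectIndex, tr))
    envI <- simulatePulseTrain(spec@trialDurationS, fs, spec@pulseRate,
                               spec@pulseWidthSigmaMs, spec@amplitudeLaw,
                               seed = .subSeed(spec@seed, subjectIndex, tr, 2L),
                               sourceId = sprintf("s%02d_t%02d_ign", subjectIndex, tr))
    sig <- .convCausal(envA@values, hAtt) + .convCausal(envI@values, hIgn)
    clean <- outer(spec@topography, sig) # channels x samples
    set.seed(.subSeed(spec@seed, subjectIndex, tr, 3L))
    noise <- t(vapply(seq_len(spec@nChannels),
                      function(i) .oneOverFNoise(n, spec@noiseExponent, fs),
                      numeric(n)))
    if (spec@spatiallyCorrelatedNoise && spec@nChannels > 1) {
      # simple half-and-half mixture with a common component
      common <- .oneOverFNoise(n, spec@noiseExponent, fs)
      noise <- sqrt(0.5) * noise + sqrt(0.5) * matrix(common, spec@nChannels, n,
                                                      byrow = TRUE)
    }
    sigPow <- mean(clean^2)
    noiPow <- mean(noise^2)
    scale <- if (sigPow > 0 && noiPow > 0)
      sqrt(sigPow / noiPow) * 10^(-spec@snrDb / 20) else 1
    eeg[[tr]] <- new("ContinuousRecording", data = clean + scale * noise,
                     fs = fs, channels = chan, reference = "synthetic")
    envs[[tr]] <- list(attended = envA, ignored = envI)
    pa <- envA@pulses; pi_ <- envI@pulses
    pulseLog[[tr]] <- rbind(
      if (nrow(pa)) data.frame(trial = tr, stream = "attended", timeS = pa$timeS,
                               sample = round(pa$timeS * fs) + 1L,
                               amplitude = pa$amplitude),
      if (nrow(pi_)) data.frame(trial = tr, stream = "ignored", timeS = pi_$timeS,
                                sample = round(pi_$timeS * fs) + 1L,
                                amplitude = pi_$amplitude))
  }
  truth <- new("GroundTruth", attendedKernel = kAtt, ignoredKernel = kIgn,
               pulses = do.call(rbind, pulseLog) %||%
                 data.frame(trial = integer(0), stream = character(0),
                            timeS = numeric(0), sample = integer(0),
                            amplitude = numeric(0)),
               topography = spec@topography,
               seed = .subSeed(spec@seed, subjectIndex))
  list(eeg = eeg, envelopes = envs, truth = truth)
}

#' Simulate a whole cohort
#'
#' Thin convenience wrapper returning one [simulateSubject()] result per
#' subject.  For large cohorts prefer generating subjects one at a time.
#'
#' @param spec a [CohortSpec-class]
#' @return list of per-subject lists
#' @export
simulateCohort <- function(spec) {
  lapply(seq_len(spec@nSubjects), function(s) simulateSubject(spec, s))
}
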