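# Audio -> onset envelope chain: gammatone filterbank, Hilbert magnitudes,
# power-law compression, 25 Hz lowpass + differentiation + half-wave
# rectification, decimation to the EEG analysis rate.

# ERB-rate spaced center frequencies (Glasberg & Moore constants as used by
# the Slaney filterbank), nBands values strictly inside [fLo, fHi]
.erbSpace <- function(fLo, fHi, nBands) {
  earQ <- 9.26449; minBW <- 24.7
  cf <- -(earQ * minBW) +
    exp(seq_len(nBands) * (-log(fHi + earQ * minBW) + log(fLo + earQ * minBW)) /
          nBands) * (fHi + earQ * minBW)
  sort(cf)
}

# Slaney 4th-order IIR gammatone coefficients for one center frequency;
# returns the feedback polynomial and the four feed-forward sections
.gammatoneCoefs <- function(cf, fs) {
  T <- 1 / fs
  earQ <- 9.26449; minBW <- 24.7
  erb <- cf / earQ + minBW
  B <- 1.019 * 2 * pi * erb
  arg <- 2 * cf * pi * T
  eB <- exp(B * T)
  cosA <- cos(arg); sinA <- sin(arg)
  sq1 <- sqrt(3 + 2^1.5); sq2 <- sqrt(3 - 2^1.5)
  A0 <- T; A2 <- 0
  B0 <- 1; B1 <- -2 * cosA / eB; B2 <- exp(-2 * B * T)
  A11 <- -(2 * T * cosA / eB + sq1 * T * sinA / eB) / 2
  A12 <- -(2 * T * cosA / eB - sq1 * T * sinA / eB) / 2
  A13 <- -(2 * T * cosA / eB + sq2 * T * sinA / eB) / 2
  A14 <- -(2 * T * cosA / eB - sq2 * T * sinA / eB) / 2
  z <- exp(2i * arg)
  num <- (-2 * z * T + 2 * exp(-B * T + 1i * arg) * T *
            (cosA - sq2 * sinA)) *
         (-2 * z * T + 2 * exp(-B * T + 1i * arg) * T *
            (cosA + sq2 * sinA)) *
         (-2 * z * T + 2 * exp(-B * T + 1i * arg) * T *
            (cosA - sq1 * sinA)) *
         (-2 * z * T + 2 * exp(-B * T + 1i * arg) * T *
            (cosA + sq1 * sinA))
  den <- (-2 / exp(2 * B * T) - 2 * z + 2 * (1 + z) / eB)^4
  gain <- abs(num / den)
  list(b = rbind(c(A0, A11, A2), c(A0, A12, A2), c(A0, A13, A2), c(A0, A14, A2)),
       a = c(B0, B1, B2), gain = gain)
}

#' Gammatone filterbank decomposition
#'
#' Decomposes an audio waveform into ERB-spaced subbands with a 4th-order
#' IIR gammatone approximation (Slaney/Patterson lineage).
#'
#' @param audio numeric waveform
#' @param fs sampling rate, Hz; must be at least \code{2 * fHi}
#' @param nBands number of subbands (default 128)
#' @param fLo,fHi frequency range of the center frequencies, Hz
#' @return list with \code{bands} (nBands x samples matrix),
#'   \code{centerFrequencies} (Hz, increasing) and \code{fs}
#' @export
gammatoneFilterbank <- function(audio, fs, nBands = 128, fLo = 100, fHi = 8000) {
  if (fs < 2 * fHi) stop("sampling rate too low: need fs >= 2 * fHi")
  cf <- .erbSpace(fLo, fHi, nBands)
  bands <- matrix(0, nBands, length(audio))
  for (i in seq_len(nBands)) {
    co <- .gammatoneCoefs(cf[i], fs)
    y <- audio
    for (s in 1:4) {
      b <- co$b[s, ]
      if (s == 1) b <- b / co$gain
      y <- signal::filter(b, co$a, y)
    }
    bands[i, ] <- y
  }
  list(bands = bands, centerFrequencies = cf, fs = fs)
}

#' Broadband envelope from a subband set
#'
#' Per band, the magnitude of the analytic signal is raised to a compressive
#' power law (default exponent 0.3, simulating loudness growth) and the
#' result is averaged across bands.
#'
#' @param subbands result of [gammatoneFilterbank()]
#' @param exponent power-law exponent
#' @return numeric broadband envelope, same length as the input samples
#' @export
broadbandEnvelope <- function(subbands, exponent = 0.3) {
  b <- subbands$bands
  env <- matrix(0, nrow(b), ncol(b))
  for (i in seq_len(nrow(b))) env[i, ] <- Mod(.analytic(b[i, ]))^exponent
  colMeans(env)
}

#' Onset envelope: emphasize acoustic edges
#'
#' Zero-phase 3rd-order Butterworth lowpass at \code{cutoffHz}, first
#' difference, half-wave rectification.  The first difference keeps the
#' series length by prepending a zero; no \code{fs} scaling is applied since
#' the downstream threshold is expressed in pooled-sigma units.
#'
#' @param broadband numeric broadband envelope
#' @param fs sampling rate, Hz (must exceed 2 * cutoffHz)
#' @param cutoffHz lowpass cutoff (default 25)
#' @return nonnegative numeric series of the same length
#' @export
onsetEnvelope <- function(broadband, fs, cutoffHz = 25) {
  if (fs <= 2 * cutoffHz) stop("fs must exceed twice the lowpass cutoff")
  if (length(broadband) < 3 * 7) stop("series too short for filter warm-up")
  bt <- signal::butter(3, cutoffHz / (fs / 2))
  sm <- signal::filtfilt(bt, broadband)
  pmax(c(0, diff(sm)), 0)
}

#' Decimate an envelope to the analysis rate
#'
#' Anti-aliased Fourier-domain resampling; output length is
#' \code{round(length(x) * fsOut / fsIn)}.  Upsampling is rejected.
#'
#' @param x numeric series or [OnsetEnvelope-class]
#' @param fsIn input rate, Hz (taken from the object if an OnsetEnvelope)
#' @param fsOut output rate, Hz (default 256)
#' @return object of the same kind at rate fsOut
#' @export
decimateEnvelope <- function(x, fsIn = NULL, fsOut = 256) {
  if (is(x, "OnsetEnvelope")) {
    fsIn <- x@fs
    if (fsOut > fsIn) stop("decimateEnvelope: upsampling rejected")
    v <- pmax(fftResample(x@values, fsIn, fsOut), 0)
    return(new("OnsetEnvelope", values = v, fs = fsOut, sourceId = x@sourceId,
               pooledSigma = NA_real_, pulses = x@pulses))
  }
  if (is.null(fsIn)) stop("fsIn required for plain numeric input")
  if (fsOut > fsIn) stop("decimateEnvelope: upsampling rejected")
  fftResample(x, fsIn, fsOut)
}

#' Normalize a pool of envelopes by their global standard deviation
#'
#' All amplitude values are divided by one pooled (population) standard
#' deviation computed across every sample of every envelope in the pool, so
#' the pooled standard deviation of the output is exactly 1.
#'
#' @param envelopes list of numeric vectors or [OnsetEnvelope-class] objects
#' @return list of the same kind, rescaled
#' @export
normalizeEnvelopes <- function(envelopes) {
  if (!length(envelopes)) stop("empty envelope pool")
  vals <- unlist(lapply(envelopes, function(e)
    if (is(e, "OnsetEnvelope")) e@values else e))
  s <- .popSd(vals)
  if (s == 0) stop("degenerate pool: zero variance, cannot normalize")
  lapply(envelopes, function(e) {
    if (is(e, "OnsetEnvelope")) {
      e@values <- e@values / s
      e@pooledSigma <- 1
      e
    } else e / s
  })
}

#' Full audio-to-onset-envelope chain
#'
#' [gammatoneFilterbank()] then [broadbandEnvelope()], [onsetEnvelope()],
#' and [decimateEnvelope()] to the analysis rate.
#'
#' @param audio numeric waveform
#' @param fs audio sampling rate, Hz
#' @param fsOut analysis rate, Hz (default 256)
#' @param nBands,fLo,fHi,exponent see the stage functions
#' @param sourceId provenance label
#' @return an [OnsetEnvelope-class] at rate fsOut
#' @export
audioToOnsetEnvelope <- function(audio, fs, fsOut = 256, nBands = 128,
                                 fLo = 100, fHi = 8000, exponent = 0.3,
                                 sourceId = "audio") {
  sb <- gammatoneFilterbank(audio, fs, nBands, fLo, fHi)
  bb <- broadbandEnvelope(sb, exponent)
  oe <- onsetEnvelope(bb, fs)
  v <- pmax(fftResample(oe, fs, fsOut), 0)
  new("OnsetEnvelope", values = v, fs = fsOut, sourceId = sourceId,
      pooledSigma = NA_real_,
      pulses = data.frame(timeS = numeric(0), amplitude = numeric(0)))
}
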