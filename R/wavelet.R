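# Analytic generalized Morse wavelets, continuous wavelet transform,
# instantaneous phase, and wavelet phase synchronization stability (WPSS).
#
# The frequency-domain form is a * w^beta * exp(-w^gamma) for w > 0 and 0
# otherwise (perfect analyticity); the "center frequency" of a scale is the
# wavelet peak frequency w_p = (beta/gamma)^(1/gamma) mapped to Hz.

#' Sampled generalized Morse wavelet
#'
#' Returns the unit-energy analytic time-domain kernel of length
#' \code{length}, centered at sample \code{floor(length/2) + 1} (stored in
#' attribute \code{center}).  Built in the frequency domain, so the spectrum
#' is exactly zero at negative frequencies.
#'
#' @param gamma,beta Morse shape parameters (> 0); the defaults (3, 3.29)
#'   give one full oscillation cycle at the peak frequency within the
#'   central energy window
#' @param centerFreqHz desired peak frequency, Hz (< fs/2)
#' @param fs sampling rate, Hz
#' @param length kernel length in samples
#' @return complex vector with attributes \code{center} and \code{freqsHz}
#' @export
morseWavelet <- function(gamma = 3, beta = 3.29, centerFreqHz, fs, length) {
  if (gamma <= 0 || beta <= 0) stop("morseWavelet: gamma and beta must be > 0")
  if (centerFreqHz >= fs / 2) stop("morseWavelet: center frequency must be < fs/2")
  n <- as.integer(length)
  wp <- (beta / gamma)^(1 / gamma)           # peak of w^beta exp(-w^gamma)
  wc <- 2 * pi * centerFreqHz / fs           # target digital frequency
  s <- wp / wc                               # scale mapping peak -> target
  k <- 0:(n - 1)
  w <- 2 * pi * k / n
  pos <- w > 0 & w < pi | (n %% 2 == 0 & k == n / 2)
  H <- numeric(n)
  sw <- s * w[pos]
  H[pos] <- exp(beta * log(sw) - sw^gamma)
  psi <- stats::fft(H, inverse = TRUE) / n   # centered at sample 1 (circular)
  ctr <- floor(n / 2) + 1L
  psi <- c(psi[(n - ctr + 2):n], psi[1:(n - ctr + 1)]) # rotate center to ctr
  psi <- psi / sqrt(sum(Mod(psi)^2))
  structure(psi, center = ctr, freqsHz = centerFreqHz)
}

#' Construct a Morse wavelet family
#'
#' Geometric scale grid with a fixed number of voices per octave between
#' inclusive endpoint frequencies (default 17 voices within 2-32 Hz, i.e.
#' 69 scales over 4 octaves).
#'
#' @param gamma,beta Morse shape parameters
#' @param fLoHz,fHiHz inclusive frequency range, Hz
#' @param voicesPerOctave scales per octave (default 17)
#' @param fs sampling rate, Hz
#' @return a [MorseFamily-class]
#' @export
morseFamily <- function(gamma = 3, beta = 3.29, fLoHz = 2, fHiHz = 32,
                        voicesPerOctave = 17, fs = 256) {
  freqs <- 2^(seq(log2(fLoHz), log2(fHiHz), by = 1 / voicesPerOctave))
  new("MorseFamily", gamma = gamma, beta = beta, freqsHz = freqs, fs = fs)
}

#' Analytic continuous wavelet transform
#'
#' Per scale, the transform at time t is the inner product of the signal
#' with the conjugated, time-shifted analytic kernel (same-length alignment
#' centered on the kernel peak):
#' \code{w(s, t) = sum_u x(u) Conj(psi_s(u - t + center))}.
#'
#' @param x numeric vector, or matrix with one sweep per column
#' @param family a [MorseFamily-class]
#' @param outIdx optional integer vector of output sample indices (1-based);
#'   default all samples
#' @return for vector input, a scales x time complex matrix; for matrix
#'   input, a scales x time x sweeps complex array
#' @export
morseCwt <- function(x, family, outIdx = NULL) {
  stopifnot(is(family, "MorseFamily"))
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(xm)
  kernels <- lapply(family@freqsHz, function(f)
    morseWavelet(family@gamma, family@beta, f, family@fs, n))
  if (n < 8) stop("morseCwt: sweep too short for the kernel support")
  outIdx <- outIdx %||% seq_len(n)
  nf <- stats::nextn(2L * n, 2)
  X <- stats::mvfft(rbind(xm, matrix(0, nf - n, ncol(xm))))
  out <- array(0i, dim = c(length(kernels), length(outIdx), ncol(xm)))
  for (si in seq_along(kernels)) {
    psi <- kernels[[si]]
    ctr <- attr(psi, "center")
    K <- stats::fft(c(Conj(rev(psi)), numeric(nf - n))) # correlation kernel
    co <- stats::mvfft(X * K, inverse = TRUE) / nf
    # full correlation index: t + (n - ctr) is where lag-0 alignment sits
    rows <- outIdx + (n - ctr)
    out[si, , ] <- co[rows, , drop = FALSE]
  }
  if (!is.matrix(x)) matrix(out[, , 1], dim(out)[1], dim(out)[2]) else out
}

#' Instantaneous phase of wavelet coefficients
#'
#' Elementwise complex argument in (-pi, pi]; exact-zero coefficients get
#' phase 0 with a logged degeneracy count.
#'
#' @param coefficients complex array from [morseCwt()]
#' @return numeric array of phases with the same shape
#' @export
instantaneousPhase <- function(coefficients) {
  zero <- coefficients == 0
  nz <- sum(zero)
  if (nz > 0)
    message(sprintf("instantaneousPhase: %d zero-magnitude cell(s) set to phase 0", nz))
  ph <- Arg(coefficients)
  ph[zero] <- 0
  ph
}

#' Wavelet phase synchronization stability across sweeps
#'
#' Per time-frequency cell, the mean resultant vector length
#' \code{|mean_k exp(i phi_k)|} of the sweeps' instantaneous phases: 1 for
#' perfect synchronization, 0 for perfect desynchronization.
#'
#' @param phases scales x time x sweeps numeric array (>= 2 sweeps)
#' @return scales x time matrix in [0, 1]
#' @export
wpss <- function(phases) {
  d <- dim(phases)
  if (is.null(d) || length(d) != 3) stop("wpss: need a scales x time x sweeps array")
  if (d[3] < 2) stop("wpss: at least 2 sweeps required")
  u <- exp(1i * phases)
  r <- Mod(rowMeans(matrix(u, d[1] * d[2], d[3]))) # mean over sweeps
  matrix(pmin(r, 1), d[1], d[2])
}

#' WPSS map of an epoch set at one channel
#'
#' Transforms every accepted sweep at the given channel with the Morse
#' family, extracts instantaneous phases, and reduces them to a
#' [WpssMap-class] over the requested output span (default -50..500 ms, the
#' reporting window; the transform itself runs on the full epoch so edge
#' effects stay outside the reported span).
#'
#' @param epochs an [EpochSet-class]
#' @param family a [MorseFamily-class] at the epoch sampling rate
#' @param channel channel label or index
#' @param spanMs output time span, ms
#' @param maxSweeps optional cap: a seeded uniform subsample of accepted
#'   sweeps to bound the resultant computation (NULL = all)
#' @param seed seed for the subsample
#' @param condition condition label stored in the map
#' @return a [WpssMap-class]
#' @export
epochWpss <- function(epochs, family, channel, spanMs = c(-50, 500),
                      maxSweeps = NULL, seed = 1, condition = "unknown") {
  stopifnot(is(epochs, "EpochSet"), is(family, "MorseFamily"))
  if (family@fs != epochs@fs) stop("epochWpss: sampling-rate mismatch")
  ch <- if (is.character(channel)) match(channel, epochs@channels) else channel
  if (is.na(ch)) stop("epochWpss: unknown channel")
  keep <- which(epochs@accepted)
  if (length(keep) < 2) stop("epochWpss: need at least 2 accepted sweeps")
  if (!is.null(maxSweeps) && length(keep) > maxSweeps) {
    set.seed(seed)
    keep <- sort(sample(keep, maxSweeps))
  }
  sweeps <- epochs@data[, ch, keep] # time x sweeps
  offs <- epochs@sampleOffsets
  outSel <- which(offs >= round(spanMs[1] / 1000 * epochs@fs) &
                  offs <= round(spanMs[2] / 1000 * epochs@fs))
  co <- morseCwt(sweeps, family, outIdx = outSel)
  u <- co / Mod(co)
  u[!is.finite(u)] <- 0 # zero-magnitude cells contribute a zero vector
  r <- Mod(apply(u, c(1, 2), mean))
  new("WpssMap", values = pmin(r, 1), freqsHz = family@freqsHz,
      timesMs = offs[outSel] / epochs@fs * 1000,
      nSweeps = length(keep),
      channel = as.character(epochs@channels[ch]), condition = condition)
}

#' Band/window mean of a WPSS map
#'
#' Arithmetic mean over all cells whose center frequency lies in
#' \code{bandHz} and whose time lies in \code{windowMs} (both inclusive);
#' e.g. the theta band (4-8 Hz) within the N1-P2 window.
#'
#' @param map a [WpssMap-class]
#' @param bandHz two-element frequency band, Hz
#' @param windowMs two-element time window, ms
#' @return scalar mean WPSS
#' @export
bandWindowMean <- function(map, bandHz = c(4, 8), windowMs) {
  stopifnot(is(map, "WpssMap"))
  fSel <- map@freqsHz >= bandHz[1] & map@freqsHz <= bandHz[2]
  tSel <- map@timesMs >= windowMs[1] & map@timesMs <= windowMs[2]
  if (!any(fSel) || !any(tSel))
    stop("bandWindowMean: empty band/window selection")
  mean(map@values[fSel, tSel])
}

#' Duration-based cycle count of a Morse wavelet
#'
#' The number of oscillation cycles at the peak frequency inside the central
#' energy window, \code{sqrt(beta * gamma) / pi} (about 1.00 for the default
#' (3, 3.29) family).
#'
#' @param gamma,beta Morse shape parameters
#' @return cycle count
#' @export
morseCycles <- function(gamma = 3, beta = 3.29) sqrt(beta * gamma) / pi
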