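# Internal numeric helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# causal linear convolution, first length(x) samples of conv(x, k)
.convCausal <- function(x, k) {
  n <- length(x); m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - n))) *
                     stats::fft(c(k, numeric(nf - m))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

# analytic signal via the frequency-domain construction
.analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Fourier-domain rational resampling (anti-aliased by spectral truncation),
# output length round(n * fsOut / fsIn); amplitude-preserving for signals
# band-limited below min(fsIn, fsOut)/2
fftResample <- function(x, fsIn, fsOut) {
  n <- length(x)
  nOut <- round(n * fsOut / fsIn)
  if (nOut == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = nOut)
  nKeep <- min(n, nOut)
  half <- floor((nKeep - 1) / 2)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(nOut - half + 1):nOut] <- X[(n - half + 1):n]
  }
  if (nKeep %% 2 == 0) {
    # shared Nyquist bin of the smaller grid: keep its real part once on each
    # conjugate side so the output stays real and symmetric
    ny <- nKeep / 2 + 1
    v <- if (nOut < n) Re(X[ny]) else X[ny] / 2
    Y[ny] <- v
    if (nOut > nKeep) Y[nOut - nKeep / 2 + 1] <- Conj(v)
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# sample-offset index range for a ms window at rate fs
.windowOffsets <- function(windowMs, fs) {
  seq.int(round(windowMs[1] / 1000 * fs), round(windowMs[2] / 1000 * fs))
}

# population standard deviation (divide by N)
.popSd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# deterministic per-stream sub-seed derived from a master seed (kept < 2^31)
.subSeed <- function(seed, ...) {
  ix <- c(...)
  as.integer((as.numeric(seed) + sum(ix * 97003L) + 12345) %% 2147483629)
}
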