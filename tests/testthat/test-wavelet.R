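# Morse wavelets, CWT, instantaneous phase, WPSS.

test_that("Morse kernels are analytic, unit-energy, and peak where asked", {
  psi <- morseWavelet(3, 3.29, centerFreqHz = 8, fs = 256, length = 512)
  P <- fft(psi)
  # negative-frequency half of the spectrum is numerically zero
  neg <- (length(P) / 2 + 2):length(P)
  expect_lt(max(Mod(P[neg])), 1e-10 * max(Mod(P)))
  expect_equal(sum(Mod(psi)^2), 1, tolerance = 1e-10)
  # spectral peak within half a bin of the requested center frequency
  fAxis <- (seq_along(P) - 1) * 256 / length(P)
  expect_lt(abs(fAxis[which.max(Mod(P))] - 8), 256 / 512 / 2 + 1e-9)
  expect_error(morseWavelet(3, 3.29, 200, 256, 256), "fs/2")
  expect_error(morseWavelet(-1, 3.29, 8, 256, 256), "> 0")
})

test_that("the (3, 3.29) family carries one cycle in its central energy window", {
  expect_equal(morseCycles(3, 3.29), sqrt(3 * 3.29) / pi)
  expect_lt(abs(morseCycles(3, 3.29) - 1), 0.01)
})

test_that("the default scale grid spans 2-32 Hz with 17 voices per octave", {
  fam <- morseFamily()
  expect_equal(length(fam@freqsHz), 69)
  expect_equal(fam@freqsHz[1], 2)
  expect_equal(fam@freqsHz[69], 32)
  expect_equal(fam@freqsHz[18] / fam@freqsHz[1], 2, tolerance = 1e-12)
})

test_that("CWT localizes tones, vanishes on zero input, matches brute force", {
  fs <- 256
  fam <- morseFamily(fLoHz = 2, fHiHz = 32, fs = fs)
  t <- (0:511) / fs
  co <- morseCwt(cos(2 * pi * 8 * t), fam)
  mag <- rowMeans(Mod(co[, 150:350]))
  expect_equal(fam@freqsHz[which.max(mag)], 8, tolerance = 8 * 2^(1 / 17) - 8)
  expect_true(all(morseCwt(numeric(256), fam) == 0))
  # brute-force convolution oracle at one scale
  set.seed(13)
  x <- rnorm(200)
  fam1 <- new("MorseFamily", gamma = 3, beta = 3.29, freqsHz = 6, fs = fs)
  got <- morseCwt(x, fam1)[1, ]
  psi <- morseWavelet(3, 3.29, 6, fs, 200)
  ctr <- attr(psi, "center")
  want <- complex(length.out = 200)
  for (tt in 1:200) {
    acc <- 0i
    for (u in 1:200) {
      k <- u - tt + ctr
      if (k >= 1 && k <= 200) acc <- acc + x[u] * Conj(psi[k])
    }
    want[tt] <- acc
  }
  expect_lt(max(Mod(got - want)), 1e-8)
})

test_that("instantaneous phase is the elementwise argument with zero handling", {
  expect_equal(instantaneousPhase(1 + 0i), 0)
  expect_equal(instantaneousPhase(0 + 1i), pi / 2)
  set.seed(3)
  z <- matrix(complex(real = rnorm(20), imaginary = rnorm(20)), 4)
  expect_equal(instantaneousPhase(z), atan2(Im(z), Re(z)))
  expect_message(ph <- instantaneousPhase(c(0 + 0i, 1i)), "zero-magnitude")
  expect_equal(ph[1], 0)
})

test_that("WPSS hits its algebraic extremes and matches the Rayleigh expectation", {
  # identical sweeps -> 1 everywhere
  ph <- array(rep(runif(12, -pi, pi), times = 5), c(3, 4, 5))
  expect_true(all(abs(wpss(ph) - 1) < 1e-12))
  # antipodal pair -> 0
  ph2 <- array(c(0.3, 0.3 + pi), c(1, 1, 2))
  expect_lt(wpss(ph2)[1, 1], 1e-12)
  expect_error(wpss(array(0, c(2, 2, 1))), "2 sweeps")
  # K iid uniform phases: E[R] ~ sqrt(pi)/2 / sqrt(K)
  set.seed(21)
  K <- 100
  reps <- replicate(10000, Mod(mean(exp(1i * runif(K, -pi, pi)))))
  expect_lt(abs(mean(reps) - sqrt(pi) / 2 / sqrt(K)), 0.01)
  # direct resultant-vector computation oracle on a random array
  set.seed(22)
  ph3 <- array(runif(3 * 4 * 6, -pi, pi), c(3, 4, 6))
  want <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4)
    want[i, j] <- Mod(mean(exp(1i * ph3[i, j, ])))
  expect_equal(wpss(ph3), want, tolerance = 1e-12)
})

test_that("WPSS is invariant to common rotation and per-sweep amplitude", {
  set.seed(5)
  ph <- array(runif(2 * 3 * 8, -pi, pi), c(2, 3, 8))
  rot <- ((ph + 1.1 + pi) %% (2 * pi)) - pi
  expect_equal(wpss(ph), wpss(rot), tolerance = 1e-12)
  # amplitude scaling never enters: phases of c*z equal phases of z
  z <- exp(1i * ph)
  amp <- array(rep(runif(8, 0.1, 10), each = 6), c(2, 3, 8))
  expect_equal(instantaneousPhase(z * amp), ph, tolerance = 1e-12)
})

test_that("epochWpss agrees with the explicit CWT + phase + resultant chain", {
  set.seed(30)
  fs <- 256
  nT <- 160
  dat <- array(rnorm(nT * 1 * 12), c(nT, 1, 12))
  ep <- new("EpochSet", data = dat, sampleOffsets = as.integer(-32:(nT - 33)),
            fs = fs, channels = "Cz",
            provenance = data.frame(trigger = 1:12, trial = 1, stream = "attended"),
            accepted = rep(TRUE, 12), baselined = TRUE)
  fam <- morseFamily(fLoHz = 4, fHiHz = 8, fs = fs)
  map <- epochWpss(ep, fam, "Cz", spanMs = c(0, 300))
  # oracle: full morseCwt per sweep, then the resultant across sweeps
  offs <- ep@sampleOffsets
  outSel <- which(offs >= 0 & offs <= round(0.3 * fs))
  co <- morseCwt(dat[, 1, ], fam, outIdx = outSel)
  want <- wpss(instantaneousPhase(co))
  expect_equal(wpssValues(map), want, tolerance = 1e-10)
  expect_equal(map@timesMs, offs[outSel] / fs * 1000)
})

test_that("band/window mean reduces maps like a double loop", {
  fam <- morseFamily(fLoHz = 2, fHiHz = 16, fs = 256)
  nF <- length(fam@freqsHz)
  tms <- seq(-50, 500, by = 1000 / 256)
  set.seed(9)
  v <- matrix(runif(nF * length(tms)), nF)
  map <- new("WpssMap", values = v, freqsHz = fam@freqsHz, timesMs = tms,
             nSweeps = 10L, channel = "Cz", condition = "attended")
  const <- new("WpssMap", values = matrix(0.6, nF, length(tms)),
               freqsHz = fam@freqsHz, timesMs = tms, nSweeps = 10L,
               channel = "Cz", condition = "attended")
  expect_equal(bandWindowMean(const, c(4, 8), c(116.7, 246.6)), 0.6)
  acc <- 0; cnt <- 0
  for (i in seq_len(nF)) for (j in seq_along(tms)) {
    if (fam@freqsHz[i] >= 4 && fam@freqsHz[i] <= 8 &&
        tms[j] >= 116.7 && tms[j] <= 246.6) { acc <- acc + v[i, j]; cnt <- cnt + 1 }
  }
  expect_equal(bandWindowMean(map, c(4, 8), c(116.7, 246.6)), acc / cnt,
               tolerance = 1e-12)
  expect_error(bandWindowMean(map, c(40, 80), c(116.7, 246.6)), "empty")
})
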