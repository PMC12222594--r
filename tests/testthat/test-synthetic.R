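# Synthetic cocktail-party generator: pulse trains, kernels, subjects.

test_that("pulse train honors the empty process and rejects bad parameters", {
  env <- simulatePulseTrain(20, 256, rate = 0, seed = 1)
  expect_equal(sum(envValues(env)), 0)
  expect_equal(nrow(env@pulses), 0)
  expect_error(simulatePulseTrain(Inf, 256, 3), "finite")
  expect_error(simulatePulseTrain(10, 256, -1), "rate")
})

test_that("pulse train is reproducible from its seed", {
  a <- simulatePulseTrain(50, 256, 3, seed = 77)
  b <- simulatePulseTrain(50, 256, 3, seed = 77)
  expect_identical(envValues(a), envValues(b))
  expect_identical(a@pulses, b@pulses)
  expect_equal(nrow(a@pulses), nrow(b@pulses))
})

test_that("default pulse statistics give ~2.7 suprathreshold triggers per second", {
  # long simulation pooled like one subject's envelope set
  envs <- lapply(1:8, function(i) simulatePulseTrain(120, 256, 3.4, seed = 300 + i))
  sigma <- pooledSigma(envs)
  nTrig <- sum(vapply(envs, function(e)
    length(extractTriggers(e, 2 * sigma)@indices), 0L))
  rate <- nTrig / (8 * 120)
  expect_gt(rate, 2.7 * 0.85)
  expect_lt(rate, 2.7 * 1.15)
  # the log-normal amplitude law leaves both supra- and sub-threshold pulses
  supra <- mean(unlist(lapply(envs, function(e) e@pulses$amplitude)) > 2 * sigma)
  expect_gt(supra, 0.7)
  expect_lt(supra, 0.9)
})

test_that("rendered kernel has the designed N1 minimum and gain identity", {
  fs <- 256
  k <- renderKernel(defaultAttendedKernel(), fs)
  tMs <- attr(k, "timesMs")
  expect_equal(length(k), round(600 / 1000 * fs))
  # analytic argmin of the Gaussian mixture sits at the N1 latency
  expect_lt(abs(tMs[which.min(k)] - 135), 4)
  # empty component list renders all zeros
  empty <- kernelSpec(data.frame(polarity = numeric(0), latencyMs = numeric(0),
                                 sigmaMs = numeric(0), amplitudeUv = numeric(0)))
  expect_true(all(renderKernel(empty, fs) == 0))
  # attention gain 1 leaves the kernel untouched sample-for-sample
  same <- ignoredKernel(defaultAttendedKernel(), gainN1 = 1)
  expect_identical(renderKernel(same, fs), renderKernel(defaultAttendedKernel(), fs))
})

test_that("kernel spec validity enforces ordering, widths and onset decay", {
  expect_error(kernelSpec(data.frame(polarity = c(1, -1), latencyMs = c(135, 80),
                                     sigmaMs = c(15, 22), amplitudeUv = c(1, 1))),
               "increasing")
  expect_error(kernelSpec(data.frame(polarity = 1, latencyMs = 80,
                                     sigmaMs = 0, amplitudeUv = 1)), "widths")
  expect_error(kernelSpec(data.frame(polarity = 1, latencyMs = 5,
                                     sigmaMs = 30, amplitudeUv = 1)), "decay")
})

test_that("noiseless EEG equals the brute-force convolution of train and kernel", {
  spec <- cohortSpec(nSubjects = 1, nTrials = 1, trialDurationS = 5,
                     nChannels = 3, snrDb = 300, pulseRate = 3, seed = 9)
  sub <- simulateSubject(spec, 1)
  envA <- envValues(sub$envelopes[[1]]$attended)
  envI <- envValues(sub$envelopes[[1]]$ignored)
  hA <- renderKernel(sub$truth@attendedKernel, spec@fsEeg)
  hI <- renderKernel(sub$truth@ignoredKernel, spec@fsEeg)
  n <- length(envA)
  # O(N K) loop oracle
  convLoop <- function(x, k) {
    y <- numeric(n)
    for (u in seq_along(k)) {
      idx <- u:n
      y[idx] <- y[idx] + x[idx - u + 1] * k[u]
    }
    y
  }
  sig <- convLoop(envA, hA) + convLoop(envI, hI)
  for (ch in 1:3) {
    got <- recMatrix(sub$eeg[[1]])[ch, ]
    want <- sub$truth@topography[ch] * sig
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
})

test_that("identical seeds give bit-identical cohorts; pulse doubling doubles EEG", {
  spec <- tinySpec(seed = 31)
  a <- simulateSubject(spec, 1)
  b <- simulateSubject(spec, 1)
  expect_identical(lapply(a$eeg, recMatrix), lapply(b$eeg, recMatrix))
  expect_identical(a$truth@pulses, b$truth@pulses)
  # linearity of the noiseless render path: doubling every pulse amplitude
  # doubles the evoked signal exactly
  env <- simulatePulseTrain(5, 256, 3, seed = 12)
  h <- renderKernel(defaultAttendedKernel(), 256)
  y1 <- edgeTRF:::.convCausal(envValues(env), h)
  y2 <- edgeTRF:::.convCausal(2 * envValues(env), h)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("1/f noise has log-log periodogram slope near -1", {
  set.seed(4)
  x <- edgeTRF:::.oneOverFNoise(2^15, 1, 256)
  sp <- spec.pgram(ts(x, frequency = 256), spans = 31, plot = FALSE, taper = 0)
  sel <- sp$freq > 1 & sp$freq < 100
  fit <- lm(log(sp$spec[sel]) ~ log(sp$freq[sel]))
  expect_lt(abs(coef(fit)[2] + 1), 0.15)
})

test_that("near-noiseless single pulse reproduces the kernel around the event", {
  fs <- 256
  spec <- cohortSpec(nSubjects = 1, nTrials = 1, trialDurationS = 12,
                     nChannels = 1, topography = 1, snrDb = 60,
                     pulseRate = 1, seed = 2)
  sub <- simulateSubject(spec, 1)
  p <- sub$truth@pulses
  p <- p[p$stream == "attended", ]
  # choose an isolated pulse (no neighbour within kernel duration)
  iso <- which(vapply(seq_len(nrow(p)), function(i)
    all(abs(p$timeS[-i] - p$timeS[i]) > 0.9), TRUE))
  skip_if(length(iso) == 0, "no isolated pulse drawn")
  i <- iso[1]
  k <- renderKernel(sub$truth@attendedKernel, fs) * p$amplitude[i]
  seg <- recMatrix(sub$eeg[[1]])[1, p$sample[i] + seq_along(k) - 1]
  # pulse has finite width: compare against kernel convolved with that pulse
  pw <- exp(-((seq(-80, 80)) / fs * 1000)^2 / (2 * spec@pulseWidthSigmaMs^2))
  kSm <- convolve(c(numeric(80), k, numeric(80)), rev(pw / sum(pw) * sum(pw)),
                  type = "open")
  expect_gt(cor(seg, k), 0.95)
})

test_that("cohort spec validity catches structural errors", {
  expect_error(cohortSpec(nSubjects = 0), "counts")
  expect_error(cohortSpec(topography = c(1, 2)), "topography")
  expect_error(cohortSpec(trialDurationS = 1, pulseRate = 3), "estimable")
  expect_error({
    spec <- cohortSpec()
    spec@topography <- c(1, 2, 3)
    simulateSubject(spec, 1)
  })
})

test_that("topography is unit norm and peaks at the designated channel", {
  g <- defaultTopography(16)
  expect_equal(sum(g^2), 1)
  expect_equal(which.max(g), 8)
  expect_equal(syntheticChannelNames(16)[8], "Cz")
})
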