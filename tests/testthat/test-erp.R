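# Epoching, baseline, rejection, matching, averaging, component measures.

mkTriggers <- function(idx, fs = 256, stream = "attended") {
  new("TriggerSequence", indices = as.integer(idx), fs = fs, threshold = 1,
      stream = stream)
}

test_that("epochs equal direct indexing and bounds are enforced", {
  set.seed(7)
  fs <- 256
  m <- matrix(rnorm(3 * 4000), 3)
  rec <- tinyRecording(m, fs = fs)
  trig <- mkTriggers(c(300, 900, 2100))
  ep <- extractEpochs(rec, trig, c(-500, 2000))
  offs <- ep@sampleOffsets
  expect_equal(range(offs), c(-128, 512))
  for (k in 1:3) for (ch in 1:3)
    expect_identical(ep@data[, ch, k], m[ch, trig@indices[k] + offs])
  # out-of-bounds triggers are dropped with a message
  expect_message(ep2 <- extractEpochs(rec, mkTriggers(c(50, 900, 3900))),
                 "dropped 2")
  expect_equal(dim(ep2@data)[3], 1L)
  # window [0, 0] gives single-sample sweeps equal to the trigger sample
  ep0 <- extractEpochs(rec, trig, c(0, 0))
  expect_equal(drop(ep0@data[1, , ]), m[, trig@indices])
  # empty trigger set is an empty EpochSet, not an error
  epE <- extractEpochs(rec, mkTriggers(integer(0)))
  expect_equal(dim(epE@data)[3], 0L)
})

test_that("baseline correction zeroes the window mean and refuses reapplication", {
  fs <- 256
  rec <- tinyRecording(matrix(rnorm(2 * 3000), 2), fs = fs)
  ep <- extractEpochs(rec, mkTriggers(c(400, 1500)))
  bc <- baselineCorrect(ep)
  sel <- bc@sampleOffsets %in% (round(-0.05 * fs):0)
  for (k in 1:2) for (ch in 1:2)
    expect_lt(abs(mean(bc@data[sel, ch, k])), 1e-12)
  # constant sweep becomes zero; zero-mean baseline stays put
  recC <- tinyRecording(matrix(7, 1, 3000), fs = fs)
  epC <- baselineCorrect(extractEpochs(recC, mkTriggers(400)))
  expect_true(all(abs(epC@data) < 1e-12))
  expect_error(baselineCorrect(bc), "already")
})

test_that("artifact rejection flags exactly the offending sweeps", {
  fs <- 256
  m <- matrix(rnorm(2 * 5000, sd = 5), 2)
  m[2, 1505] <- 150 # one bad sample inside the second epoch only
  rec <- tinyRecording(m, fs = fs)
  ep <- baselineCorrect(extractEpochs(rec, mkTriggers(c(400, 1500, 2800))))
  rj <- rejectArtifacts(ep, 100)
  # oracle: exhaustive max-abs scan
  want <- vapply(1:3, function(k) max(abs(ep@data[, , k])) <= 100, TRUE)
  expect_identical(rj@accepted, want)
  expect_false(rj@accepted[2])
  # all-quiet epochs survive; bad threshold errors
  expect_true(all(rejectArtifacts(ep, 1e6)@accepted))
  expect_error(rejectArtifacts(ep, -1), "positive")
})

test_that("sweep matching is exact, seeded, and near-uniform", {
  fs <- 256
  rec <- tinyRecording(matrix(rnorm(1 * 60000), 1), fs = fs)
  trigA <- mkTriggers(seq(200, 59000, by = 400))
  trigI <- mkTriggers(seq(330, 45000, by = 400), stream = "ignored")
  epA <- baselineCorrect(extractEpochs(rec, trigA))
  epI <- baselineCorrect(extractEpochs(rec, trigI))
  m1 <- matchSweepCounts(epA, epI, seed = 9)
  expect_equal(sum(m1$attended@accepted), sum(epI@accepted))
  m2 <- matchSweepCounts(epA, epI, seed = 9)
  expect_identical(m1$attended@provenance, m2$attended@provenance)
  # n equal to the available count keeps every sweep
  mAll <- matchSweepCounts(epA, epA, n = sum(epA@accepted), seed = 1)
  expect_equal(sum(mAll$attended@accepted), sum(epA@accepted))
  expect_error(matchSweepCounts(epA, epI, n = 1e6), "need")
  # uniformity: each of 200 sweeps picked with frequency ~ 1/2 for n = 100
  cnt <- numeric(200)
  for (i in 1:4000) { set.seed(i); idx <- sample(200, 100); cnt[idx] <- cnt[idx] + 1 }
  expect_lt(max(abs(cnt / 4000 - 0.5)), 0.03)
})

test_that("averaging matches loop summation and respects the rejection mask", {
  fs <- 256
  rec <- tinyRecording(matrix(rnorm(2 * 9000), 2), fs = fs)
  ep <- baselineCorrect(extractEpochs(rec, mkTriggers(c(400, 1500, 2800, 5000))))
  avg <- averageErp(ep)
  want <- matrix(0, 2, length(ep@sampleOffsets))
  for (k in 1:4) want <- want + t(ep@data[, , k])
  expect_equal(waveMatrix(avg), want / 4, tolerance = 1e-12)
  # single sweep averages to itself; opposite sweeps cancel
  ep1 <- ep; ep1@accepted <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(waveMatrix(averageErp(ep1)), t(ep@data[, , 1]))
  ep2 <- ep
  ep2@data[, , 2] <- -ep2@data[, , 1]
  ep2@accepted <- c(TRUE, TRUE, FALSE, FALSE)
  expect_lt(max(abs(waveMatrix(averageErp(ep2)))), 1e-12)
  ep@accepted[] <- FALSE
  expect_error(averageErp(ep), "no accepted")
  # linearity: windowed mean of the average equals average of windowed means
  ep3 <- baselineCorrect(extractEpochs(rec, mkTriggers(c(400, 1500, 2800))),
                         c(-50, 0))
  wave <- averageErp(ep3)
  perSweep <- vapply(1:3, function(k) {
    w <- new("Waveform", data = t(ep3@data[, , k]),
             timesMs = ep3@sampleOffsets / fs * 1000, fs = fs,
             channels = ep3@channels)
    componentAmplitude(w, 1, 135)
  }, 0)
  expect_equal(componentAmplitude(wave, 1, 135), mean(perSweep), tolerance = 1e-12)
})

test_that("peak latency finds analytic extrema and breaks ties early", {
  fs <- 256
  tMs <- (0:255) / fs * 1000
  # 5 Hz cosine: negative peak at 100 ms
  wave <- new("Waveform", data = matrix(cos(2 * pi * 5 * tMs / 1000), 1),
              timesMs = tMs, fs = fs, channels = "Cz")
  expect_equal(peakLatency(wave, "Cz", "negative", c(80, 120)), 100,
               tolerance = 1000 / fs / 2)
  flat <- new("Waveform", data = matrix(1, 1, 256), timesMs = tMs, fs = fs,
              channels = "Cz")
  expect_warning(lat <- peakLatency(flat, "Cz", "negative", c(50, 100)), "flat")
  expect_equal(lat, min(tMs[tMs >= 50 & tMs <= 100]))
  expect_error(peakLatency(wave, "Cz", "negative", c(2000, 3000)), "empty")
})

test_that("component amplitudes integrate the kernel windows correctly", {
  fs <- 256
  k <- renderKernel(defaultAttendedKernel(), fs)
  tMs <- attr(k, "timesMs")
  wave <- new("Waveform", data = matrix(k, 1), timesMs = tMs, fs = fs,
              channels = "Cz")
  # constant waveform returns the constant
  const <- new("Waveform", data = matrix(3, 1, length(tMs)), timesMs = tMs,
               fs = fs, channels = "Cz")
  expect_equal(componentAmplitude(const, "Cz", 135), 3)
  # windowed mean of the analytic kernel around N1
  sel <- tMs >= 115 & tMs <= 155
  want <- mean(k[sel])
  got <- componentAmplitude(wave, "Cz", 135)
  expect_lt(abs(got - want), 0.1 * abs(want))
  expect_lt(got, 0)
  # attended N1-P2 exceeds the ignored one by construction (gain 0.4)
  ki <- renderKernel(ignoredKernel(), fs)
  waveI <- new("Waveform", data = matrix(ki, 1), timesMs = tMs, fs = fs,
               channels = "Cz")
  expect_gt(n1p2Amplitude(wave, "Cz", 135, 225),
            n1p2Amplitude(waveI, "Cz", 135, 225))
  expect_error(componentAmplitude(wave, "Cz", 5000), "outside")
})
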