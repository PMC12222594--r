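# Lagged designs, ridge regression, TRF fitting/postprocessing, decoders.

test_that("lag grids are consecutive integers on the sample scale", {
  g <- lagGrid(-250, 700, 256)
  expect_equal(g@lags, seq.int(round(-0.25 * 256), round(0.7 * 256)))
  expect_equal(length(g@lags), 244)
  gb <- lagGrid(0, 500, 256)
  expect_equal(range(gb@lags), c(0, 128))
})

test_that("lagged designs reproduce impulse patterns and the convolution sum", {
  fs <- 256
  g0 <- lagGrid(0, 0, fs)
  x <- rnorm(50)
  expect_equal(drop(buildLaggedDesign(x, g0, "forward")), x)
  # impulse with forward lags 0..3 forms the shifted-identity pattern
  g3 <- new("LagGrid", tauMinMs = 0, tauMaxMs = 3000 / fs * 1000 / 1000,
            fs = fs, lags = 0:3)
  imp <- c(1, numeric(7))
  D <- buildLaggedDesign(imp, lagGrid(0, 3 / fs * 1000, fs), "forward")
  expect_equal(D[1:4, ], diag(4))
  # S h equals the direct double-sum oracle
  set.seed(17)
  s <- rnorm(300)
  grid <- lagGrid(-50, 150, fs)
  h <- rnorm(length(grid@lags))
  pred <- drop(buildLaggedDesign(s, grid, "forward") %*% h)
  want <- numeric(300)
  for (t in 1:300) {
    acc <- 0
    for (l in seq_along(grid@lags)) {
      u <- t - grid@lags[l]
      if (u >= 1 && u <= 300) acc <- acc + s[u] * h[l]
    }
    want[t] <- acc
  }
  expect_lt(max(abs(pred - want)), 1e-10)
  # backward design columns index the future of each channel
  m <- cbind(rnorm(60), rnorm(60))
  gb <- lagGrid(0, 5 / fs * 1000, fs)
  Db <- buildLaggedDesign(m, gb, "backward")
  expect_equal(ncol(Db), 2 * length(gb@lags))
  expect_equal(Db[10, 3], m[12, 1]) # lag +2 of channel 1
  expect_equal(Db[10, length(gb@lags) + 3], m[12, 2])
  expect_error(buildLaggedDesign(rnorm(3), grid, "forward"), "shorter")
})

test_that("ridge solutions match OLS at lambda 0 and shrink to zero", {
  set.seed(19)
  X <- matrix(rnorm(60 * 4), 60)
  y <- rnorm(60)
  expect_equal(ridgeSolve(X, y, 0), unname(coef(lm.fit(X, y))), tolerance = 1e-8)
  expect_lt(max(abs(ridgeSolve(X, y, 1e12))), 1e-6)
  # hand-assembled 3x3 normal-equation oracle, integer data, lambda = 1
  Xi <- matrix(c(1, 2, 0, 1, 3, 1,
                 2, 1, 1, 0, 1, 2,
                 0, 1, 3, 1, 2, 1), 6, 3)
  yi <- c(1, 0, 2, 1, 3, 1)
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (i in 1:3) for (j in 1:3) A[i, j] <- sum(Xi[, i] * Xi[, j])
  diag(A) <- diag(A) + 1
  for (i in 1:3) b[i] <- sum(Xi[, i] * yi)
  expect_equal(ridgeSolve(Xi, yi, 1), drop(solve(A, b)), tolerance = 1e-12)
  # singular system at lambda 0 errors
  Xs <- cbind(1:5, 2 * (1:5))
  expect_error(ridgeSolve(Xs, rnorm(5), 0), "singular")
  expect_error(ridgeSolve(X, y, -1), "lambda")
})

test_that("multi-lambda averaging equals the mean of single-lambda solves", {
  set.seed(23)
  fs <- 256
  grid <- lagGrid(0, 100, fs)
  stim <- lapply(1:3, function(i) rnorm(400))
  eeg <- lapply(1:3, function(i) matrix(rnorm(400 * 2), 400, 2))
  lams <- c(0.5, 20, 1e3)
  fit <- fitTrf(stim, eeg, grid, lams)
  # oracle: explicit per-lambda ridge on the concatenated design
  Xall <- do.call(rbind, lapply(stim, function(s)
    buildLaggedDesign(s, grid, "forward")))
  Yall <- do.call(rbind, eeg)
  W <- Reduce(`+`, lapply(lams, function(l) {
    A <- crossprod(Xall); diag(A) <- diag(A) + l
    solve(A, crossprod(Xall, Yall))
  })) / 3
  expect_equal(unname(modelWeights(fit)), unname(W), tolerance = 1e-6)
  # single lambda reduces to ridgeSolve on concatenated trials
  fit1 <- fitTrf(stim, eeg, grid, 2)
  expect_equal(unname(modelWeights(fit1)),
               unname(ridgeSolve(Xall, Yall, 2)), tolerance = 1e-6)
  # all-zero stimulus gives an all-zero TRF for every lambda
  z <- lapply(1:3, function(i) numeric(400))
  expect_true(all(modelWeights(fitTrf(z, eeg, grid, lams)) == 0))
  expect_error(fitTrf(stim[1:2], eeg, grid), "matching")
})

test_that("TRF is equivariant to stimulus delay", {
  set.seed(29)
  fs <- 256
  env <- simulatePulseTrain(20, fs, 3, seed = 51)
  h <- renderKernel(defaultAttendedKernel(), fs)[1:100]
  y <- edgeTRF:::.convCausal(envValues(env), h)
  grid <- lagGrid(-100, 500, fs)
  d <- 5
  sDel <- c(numeric(d), envValues(env)[1:(length(y) - d)])
  w0 <- modelWeights(fitTrf(list(envValues(env)), list(matrix(y)), grid, 1e-4))
  wD <- modelWeights(fitTrf(list(sDel), list(matrix(y)), grid, 1e-4))
  # delaying s by d shifts h by -d lags (interior of the 155-lag grid)
  mid <- 30:140
  expect_gt(cor(w0[mid, 1], wD[mid - d, 1]), 0.999)
})

test_that("noiseless TRF recovery correlates > 0.99 with the generating kernel", {
  spec <- cohortSpec(nSubjects = 1, nTrials = 4, trialDurationS = 20,
                     nChannels = 2, snrDb = 300, seed = 41)
  sub <- simulateSubject(spec, 1)
  eeg <- lapply(sub$eeg, function(r) trimEdges(r, 1))
  env <- lapply(sub$envelopes, function(e) trimEdges(e$attended, 1))
  fit <- fitTrf(env, eeg, lagGrid(-250, 700, spec@fsEeg), 1e-6)
  wave <- postprocessTrf(fit)
  rec <- trfKernelRecovery(wave, sub$truth@attendedKernel, channel = 1)
  expect_gt(rec$r, 0.99)
})

test_that("TRF postprocessing trims to -50..500 ms and smooths ripple", {
  fs <- 256
  grid <- lagGrid(-250, 700, fs)
  W <- matrix(rnorm(length(grid@lags) * 2), ncol = 2)
  model <- new("LinearModel", direction = "forward", weights = W,
               lagGrid = grid, lambdas = 1, channels = c("a", "b"),
               trials = 1L, postprocessed = FALSE)
  wave <- postprocessTrf(model)
  expect_equal(range(wave@timesMs), c(-13 / fs * 1000, 128 / fs * 1000))
  expect_gte(min(wave@timesMs), -51)
  expect_lte(max(wave@timesMs), 500)
  # constant row baselines to zero
  modelC <- model
  modelC@weights <- matrix(5, length(grid@lags), 2)
  expect_lt(max(abs(waveMatrix(postprocessTrf(modelC)))), 1e-6)
  # injected 60 Hz ripple is attenuated by > 20 dB
  ripple <- sin(2 * pi * 60 * grid@lags / fs)
  modelR <- model
  modelR@weights <- matrix(ripple, ncol = 1)[, c(1, 1)]
  out <- waveMatrix(postprocessTrf(modelR))[1, ]
  inIdx <- grid@lags %in% round(-0.05 * fs):round(0.5 * fs)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(ripple[inIdx]^2)), 10^(-20 / 20))
  expect_error(postprocessTrf(fitDecoder(
    list(matrix(rnorm(400), ncol = 1)), list(rnorm(400)),
    lagGrid(0, 100, fs), 1)), "forward")
})

test_that("decoders reconstruct identity mappings and fail on noise", {
  set.seed(31)
  fs <- 256
  s <- lapply(1:4, function(i) rnorm(600))
  eegCopy <- lapply(s, function(v) matrix(v, ncol = 1))
  grid <- lagGrid(0, 100, fs)
  dec <- fitDecoder(eegCopy, s, grid, 1e-8)
  sHat <- applyDecoder(dec, eegCopy[[1]])
  expect_gt(cor(sHat, s[[1]]), 0.999)
  # EEG independent of the stimulus: held-out r near zero
  noise <- lapply(1:6, function(i) matrix(rnorm(600 * 2), ncol = 2))
  loo <- looReconstruction(noise, s[c(1, 2, 3, 4, 1, 2)], grid, c(1, 100))
  expect_lt(abs(loo$meanR), 3 / sqrt(600))
  expect_equal(length(loo$perTrialR), 6)
})

test_that("leave-one-out bookkeeping and label shuffling behave as designed", {
  set.seed(37)
  fs <- 256
  spec <- cohortSpec(nSubjects = 1, nTrials = 6, trialDurationS = 15,
                     nChannels = 2, snrDb = 5, seed = 43)
  sub <- simulateSubject(spec, 1)
  eeg <- normalizeEeg(lapply(sub$eeg, function(r) trimEdges(r, 1)))
  env <- normalizeEnvelopes(lapply(sub$envelopes, function(e)
    trimEdges(e$attended, 1)))
  loo <- looReconstruction(eeg, env, lagGrid(0, 500, fs), defaultLambdas(5))
  expect_equal(length(loo$perTrialR), 6) # each trial held out exactly once
  expect_gt(loo$meanR, 0.2)
  # shuffling the stimulus labels destroys reconstruction
  shuffled <- env[c(4, 5, 6, 1, 2, 3)]
  looS <- looReconstruction(eeg, shuffled, lagGrid(0, 500, fs), defaultLambdas(5))
  expect_lt(looS$meanR, loo$meanR / 3)
  expect_lt(abs(looS$meanR), 0.1)
  expect_error(looReconstruction(eeg[1:2], env[1:2]), "3 trials")
  # per-trial-average and concatenated schemes agree on exchangeable data
  looC <- looReconstruction(eeg, env, lagGrid(0, 500, fs), defaultLambdas(5),
                            scheme = "concatenated")
  expect_equal(length(looC$perTrialR), 6)
})

test_that("channel-wise SR helper agrees with looReconstruction", {
  spec <- cohortSpec(nSubjects = 1, nTrials = 4, trialDurationS = 12,
                     nChannels = 3, snrDb = 0, seed = 47)
  sub <- simulateSubject(spec, 1)
  eeg <- normalizeEeg(lapply(sub$eeg, function(r) trimEdges(r, 1)))
  envA <- lapply(sub$envelopes, function(e) trimEdges(e$attended, 1))
  envI <- lapply(sub$envelopes, function(e) trimEdges(e$ignored, 1))
  norm <- normalizeEnvelopes(c(envA, envI))
  sA <- norm[1:4]; sI <- norm[5:8]
  grid <- lagGrid(0, 500, spec@fsEeg)
  lams <- defaultLambdas(5)
  sr <- edgeTRF:::.channelwiseSr(eeg, sA, sI, grid, lams, channels = 2)
  ref <- looReconstruction(eeg, sA, grid, lams, channels = 2)
  expect_equal(sr$attended[1], ref$meanR, tolerance = 1e-8)
})
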