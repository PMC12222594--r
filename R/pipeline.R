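# End-to-end orchestration on synthetic cohorts: per-subject chain (filter,
# trim, trigger, epoch, average, TRF, WPSS, channel-wise stimulus
# reconstruction) and cohort-level measures/statistics.

# operator matrices for the restricted-output analytic CWT: rows are
# (scale, out-time) pairs of Conj(psi_s(u - t + center)); real/imag split so
# the heavy multiply runs in real BLAS
.wpssOperator <- function(family, n, outIdx) {
  rowsR <- vector("list", length(family@freqsHz))
  rowsI <- vector("list", length(family@freqsHz))
  for (si in seq_along(family@freqsHz)) {
    psi <- morseWavelet(family@gamma, family@beta, family@freqsHz[si],
                        family@fs, n)
    ctr <- attr(psi, "center")
    pad <- c(rep(0, n), Conj(psi), rep(0, n))
    M <- matrix(0i, length(outIdx), n)
    for (j in seq_along(outIdx))
      M[j, ] <- pad[(1:n) + n + ctr - outIdx[j]]
    rowsR[[si]] <- Re(M)
    rowsI[[si]] <- Im(M)
  }
  list(Wr = do.call(rbind, rowsR), Wi = do.call(rbind, rowsI),
       nFreq = length(family@freqsHz), nTime = length(outIdx))
}

# WPSS matrix (freq x outTime) from time x sweeps real sweeps
.wpssFromSweeps <- function(op, sweeps) {
  Cr <- op$Wr %*% sweeps
  Ci <- op$Wi %*% sweeps
  modC <- sqrt(Cr^2 + Ci^2)
  modC[modC == 0] <- 1 # zero-magnitude cells contribute a zero unit vector
  mr <- rowMeans(Cr / modC)
  mi <- rowMeans(Ci / modC)
  matrix(pmin(sqrt(mr^2 + mi^2), 1), op$nFreq, op$nTime)
}

#' Default component search windows
#'
#' Peak search windows on the attended-condition grand average at the
#' designated channel: N1 in 80-180 ms (negative), P2 in 180-280 ms
#' (positive).
#' @return list with \code{n1} and \code{p2} two-element windows in ms
#' @export
defaultPeakWindows <- function() list(n1 = c(80, 180), p2 = c(180, 280))

#' Analyze one simulated subject
#'
#' Runs the single-subject chain: band-pass 1-45 Hz and 30 Hz low-pass on
#' the EEG, edge trimming, pooled 2-sigma trigger extraction, epoching with
#' baseline correction / artifact rejection / sweep-count matching, ERP
#' averaging, forward TRF fitting with postprocessing, theta-band WPSS maps,
#' and channel-wise leave-one-trial-out stimulus reconstruction.
#'
#' @param sub result of [simulateSubject()]
#' @param include character subset of c("erp", "trf", "wpss", "sr")
#' @param channels channel indices for the WPSS/SR stages (default all)
#' @param wpssMaxSweeps sweep cap for the WPSS resultant (default 400)
#' @param wpssSpanMs time span of the stored WPSS maps (default 40..320 ms,
#'   generously bracketing the N1-P2 window)
#' @param matchSeed seed for sweep matching and WPSS subsampling
#' @param trfGrid,srGrid lag grids (defaults -250..700 and 0..500 ms)
#' @param lambdas regularization grid
#' @return list with per-condition ERP/TRF [Waveform-class]s, WPSS maps,
#'   SR accuracies, matched sweep count and trigger statistics
#' @export
analyzeSubject <- function(sub, include = c("erp", "trf", "wpss", "sr"),
                           channels = NULL, wpssMaxSweeps = 400,
                           wpssSpanMs = c(40, 320), matchSeed = 1,
                           trfGrid = NULL, srGrid = NULL,
                           lambdas = defaultLambdas()) {
  fs <- sub$eeg[[1]]@fs
  nTrials <- length(sub$eeg)
  channels <- channels %||% seq_along(sub$eeg[[1]]@channels)
  # EEG conditioning: band-pass, ERP low-pass, edge trimming
  eeg <- lapply(sub$eeg, function(r)
    trimEdges(lowpassFilter(bandpassFilter(r), 30), 1))
  envA <- lapply(sub$envelopes, function(e) trimEdges(e$attended, 1))
  envI <- lapply(sub$envelopes, function(e) trimEdges(e$ignored, 1))
  sigma <- pooledSigma(c(envA, envI))
  thr <- 2 * sigma
  trigA <- lapply(seq_len(nTrials), function(tr)
    extractTriggers(envA[[tr]], thr, stream = "attended"))
  trigI <- lapply(seq_len(nTrials), function(tr)
    extractTriggers(envI[[tr]], thr, stream = "ignored"))
  nSamp <- ncol(eeg[[1]]@data)
  durS <- nSamp / fs
  triggerRate <- (sum(vapply(trigA, function(t) length(t@indices), 0L)) +
                  sum(vapply(trigI, function(t) length(t@indices), 0L))) /
                 (2 * nTrials * durS)
  out <- list(sigmaEnv = sigma, triggerRate = triggerRate,
              channels = sub$eeg[[1]]@channels)
  needEpochs <- any(c("erp", "wpss") %in% include)
  if (needEpochs) {
    epA <- combineEpochs(lapply(seq_len(nTrials), function(tr)
      extractEpochs(eeg[[tr]], trigA[[tr]], trial = tr)))
    epI <- combineEpochs(lapply(seq_len(nTrials), function(tr)
      extractEpochs(eeg[[tr]], trigI[[tr]], trial = tr)))
    epA <- rejectArtifacts(baselineCorrect(epA))
    epI <- rejectArtifacts(baselineCorrect(epI))
    matched <- matchSweepCounts(epA, epI, seed = matchSeed)
    out$nMatchedSweeps <- sum(matched$attended@accepted)
    if ("erp" %in% include) {
      out$erp <- list(attended = averageErp(matched$attended),
                      ignored = averageErp(matched$ignored))
    }
    if ("wpss" %in% include) {
      fam <- morseFamily(fLoHz = 4, fHiHz = 8, fs = fs)
      offs <- matched$attended@sampleOffsets
      outSel <- which(offs >= round(wpssSpanMs[1] / 1000 * fs) &
                      offs <= round(wpssSpanMs[2] / 1000 * fs))
      op <- .wpssOperator(fam, length(offs), outSel)
      tAxis <- offs[outSel] / fs * 1000
      pickSweeps <- function(ep) {
        keep <- which(ep@accepted)
        if (length(keep) > wpssMaxSweeps) {
          set.seed(matchSeed)
          keep <- sort(sample(keep, wpssMaxSweeps))
        }
        keep
      }
      kA <- pickSweeps(matched$attended)
      kI <- pickSweeps(matched$ignored)
      out$wpss <- list(
        attended = lapply(channels, function(ch)
          new("WpssMap",
              values = .wpssFromSweeps(op, matched$attended@data[, ch, kA]),
              freqsHz = fam@freqsHz, timesMs = tAxis,
              nSweeps = length(kA),
              channel = as.character(out$channels[ch]), condition = "attended")),
        ignored = lapply(channels, function(ch)
          new("WpssMap",
              values = .wpssFromSweeps(op, matched$ignored@data[, ch, kI]),
              freqsHz = fam@freqsHz, timesMs = tAxis,
              nSweeps = length(kI),
              channel = as.character(out$channels[ch]), condition = "ignored")))
    }
    rm(epA, epI, matched)
  }
  if (any(c("trf", "sr") %in% include)) {
    eegN <- normalizeEeg(eeg)
    envN <- normalizeEnvelopes(c(envA, envI))
    sA <- envN[seq_len(nTrials)]
    sI <- envN[nTrials + seq_len(nTrials)]
    if ("trf" %in% include) {
      grid <- trfGrid %||% lagGrid(-250, 700, fs)
      out$trf <- list(
        attended = postprocessTrf(fitTrf(sA, eegN, grid, lambdas)),
        ignored = postprocessTrf(fitTrf(sI, eegN, grid, lambdas)))
    }
    if ("sr" %in% include) {
      grid <- srGrid %||% lagGrid(0, 500, fs)
      sr <- .channelwiseSr(eegN, sA, sI, grid, lambdas, channels)
      out$sr <- sr
    }
  }
  out
}

# channel-wise leave-one-trial-out reconstruction for both conditions,
# sharing the per-(trial, channel) EEG autocovariance between conditions
.channelwiseSr <- function(eegN, stimA, stimI, grid, lambdas, channels) {
  nTrials <- length(eegN)
  vaA <- lapply(stimA, function(s) if (is(s, "OnsetEnvelope")) s@values else s)
  vaI <- lapply(stimI, function(s) if (is(s, "OnsetEnvelope")) s@values else s)
  rA <- matrix(NA_real_, nTrials, length(channels))
  rI <- matrix(NA_real_, nTrials, length(channels))
  L <- length(grid@lags)
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    wA <- matrix(0, L, nTrials)
    wI <- matrix(0, L, nTrials)
    for (tr in seq_len(nTrials)) {
      X <- buildLaggedDesign(matrix(eegN[[tr]]@data[ch, ], ncol = 1), grid,
                             "backward")
      XtX <- crossprod(X)
      B <- crossprod(X, cbind(vaA[[tr]], vaI[[tr]]))
      W <- .solveAveraged(XtX, B, lambdas)
      wA[, tr] <- W[, 1]
      wI[, tr] <- W[, 2]
    }
    sumA <- rowSums(wA); sumI <- rowSums(wI)
    for (tr in seq_len(nTrials)) {
      X <- buildLaggedDesign(matrix(eegN[[tr]]@data[ch, ], ncol = 1), grid,
                             "backward")
      gA <- (sumA - wA[, tr]) / (nTrials - 1)
      gI <- (sumI - wI[, tr]) / (nTrials - 1)
      rA[tr, ci] <- stats::cor(drop(X %*% gA), vaA[[tr]])
      rI[tr, ci] <- stats::cor(drop(X %*% gI), vaI[[tr]])
    }
  }
  list(attended = colMeans(rA), ignored = colMeans(rI))
}

#' Analyze a synthetic cohort end to end
#'
#' Runs [analyzeSubject()] for every subject (generating each on the fly),
#' then derives the group-level quantities: grand-average waveforms,
#' component windows from the attended grand average at the
#' peak-topography channel, per-subject N1-P2 amplitudes (ERP and TRF),
#' theta-band N1-P2-window WPSS, channel-wise stimulus-reconstruction
#' accuracies, the four attention-decoding t-maps, and ERP-TRF similarity
#' statistics.
#'
#' @param spec a [CohortSpec-class]
#' @param include stages to run (subset of c("erp", "trf", "wpss", "sr"))
#' @param channels channel indices for WPSS/SR (default all)
#' @param wpssMaxSweeps sweep cap for WPSS resultants
#' @param verbose print progress
#' @return a list with per-subject results (\code{subjects}), grand
#'   averages, component windows, per-subject measure matrices
#'   (\code{measures$<name>$attended/ignored}, subjects x channels), t-maps,
#'   and ERP-TRF comparison results
#' @export
cohortAnalysis <- function(spec, include = c("erp", "trf", "wpss", "sr"),
                           channels = NULL, wpssMaxSweeps = 400,
                           verbose = FALSE) {
  nCh <- spec@nChannels
  channels <- channels %||% seq_len(nCh)
  peakCh <- which.max(spec@topography)
  subs <- vector("list", spec@nSubjects)
  for (s in seq_len(spec@nSubjects)) {
    if (verbose) message(sprintf("subject %d/%d", s, spec@nSubjects))
    sim <- simulateSubject(spec, s)
    subs[[s]] <- analyzeSubject(sim, include = include, channels = channels,
                                wpssMaxSweeps = wpssMaxSweeps,
                                matchSeed = .subSeed(spec@seed, s, 999L))
    rm(sim)
  }
  out <- list(spec = spec, subjects = subs, peakChannel = peakCh,
              channelNames = subs[[1]]$channels,
              triggerRate = mean(vapply(subs, `[[`, 0, "triggerRate")))
  win <- defaultPeakWindows()
  measures <- list()
  subjMat <- function(f, k) { # subjects x k matrix even when k == 1
    v <- vapply(subs, f, numeric(k))
    if (k == 1) matrix(v, ncol = 1) else t(v)
  }
  grandWave <- function(field, cond) {
    ws <- lapply(subs, function(x) x[[field]][[cond]])
    w <- ws[[1]]
    w@data <- Reduce(`+`, lapply(ws, function(v) v@data)) / length(ws)
    w
  }
  if ("erp" %in% include) {
    out$grandErp <- list(attended = grandWave("erp", "attended"),
                         ignored = grandWave("erp", "ignored"))
    gA <- cropWaveform(out$grandErp$attended)
    out$erpPeaks <- c(
      n1 = peakLatency(gA, peakCh, "negative", win$n1),
      p2 = peakLatency(gA, peakCh, "positive", win$p2))
    measures$erpN1p2 <- list(
      attended = subjMat(function(x) vapply(seq_len(nCh), function(ch)
        n1p2Amplitude(x$erp$attended, ch, out$erpPeaks["n1"],
                      out$erpPeaks["p2"]), 0), nCh),
      ignored = subjMat(function(x) vapply(seq_len(nCh), function(ch)
        n1p2Amplitude(x$erp$ignored, ch, out$erpPeaks["n1"],
                      out$erpPeaks["p2"]), 0), nCh))
  }
  if ("trf" %in% include) {
    out$grandTrf <- list(attended = grandWave("trf", "attended"),
                         ignored = grandWave("trf", "ignored"))
    gT <- out$grandTrf$attended
    out$trfPeaks <- c(
      n1 = peakLatency(gT, peakCh, "negative", win$n1),
      p2 = peakLatency(gT, peakCh, "positive", win$p2))
    measures$trfN1p2 <- list(
      attended = subjMat(function(x) vapply(seq_len(nCh), function(ch)
        n1p2Amplitude(x$trf$attended, ch, out$trfPeaks["n1"],
                      out$trfPeaks["p2"]), 0), nCh),
      ignored = subjMat(function(x) vapply(seq_len(nCh), function(ch)
        n1p2Amplitude(x$trf$ignored, ch, out$trfPeaks["n1"],
                      out$trfPeaks["p2"]), 0), nCh))
  }
  if ("wpss" %in% include && "erp" %in% include) {
    wpssWin <- c(out$erpPeaks["n1"] - 20, out$erpPeaks["p2"] + 20)
    out$wpssWindowMs <- unname(wpssWin)
    measures$wpssTheta <- list(
      attended = subjMat(function(x) vapply(seq_along(channels),
        function(ci) bandWindowMean(x$wpss$attended[[ci]], c(4, 8), wpssWin), 0),
        length(channels)),
      ignored = subjMat(function(x) vapply(seq_along(channels),
        function(ci) bandWindowMean(x$wpss$ignored[[ci]], c(4, 8), wpssWin), 0),
        length(channels)))
  }
  if ("sr" %in% include) {
    measures$srAccuracy <- list(
      attended = subjMat(function(x) x$sr$attended, length(channels)),
      ignored = subjMat(function(x) x$sr$ignored, length(channels)))
  }
  out$measures <- measures
  out$tMaps <- lapply(measures, function(m) decodingTmap(m$attended, m$ignored))
  if (all(c("erp", "trf") %in% include)) {
    erpA <- lapply(subs, function(x) cropWaveform(x$erp$attended))
    trfA <- lapply(subs, function(x) x$trf$attended)
    out$bestLagSamples <- bestLag(erpA, trfA, channel = peakCh)
    gErp <- cropWaveform(out$grandErp$attended)
    gTrf <- shiftWaveform(out$grandTrf$attended, out$bestLagSamples)
    if (nCh >= 3)
      out$topoCourse <- topographicSimilarityCourse(gErp, gTrf)
    out$waveformR <- waveformCorrelationPerChannel(gErp, gTrf)
  }
  out
}

#' TRF-kernel recovery correlation
#'
#' Pearson correlation between a postprocessed TRF at one channel and the
#' generating kernel sampled on the same lag grid, after integer lag
#' alignment (the recovery check for the synthetic generator).
#'
#' @param trfWave postprocessed TRF [Waveform-class]
#' @param kernel the generating [KernelSpec-class]
#' @param channel channel label or index (default the waveform's largest-RMS
#'   channel)
#' @param maxLag lag search range in samples
#' @return list with \code{r} (correlation at the best lag) and \code{lag}
#' @export
trfKernelRecovery <- function(trfWave, kernel, channel = NULL, maxLag = 16) {
  stopifnot(is(trfWave, "Waveform"), is(kernel, "KernelSpec"))
  ch <- channel %||% which.max(sqrt(rowMeans(trfWave@data^2)))
  if (is.character(ch)) ch <- match(ch, trfWave@channels)
  k <- numeric(length(trfWave@timesMs))
  cmp <- kernel@components
  for (i in seq_len(nrow(cmp)))
    k <- k + cmp$polarity[i] * cmp$amplitudeUv[i] *
      exp(-(trfWave@timesMs - cmp$latencyMs[i])^2 / (2 * cmp$sigmaMs[i]^2))
  lag <- bestLag(k, trfWave@data[ch, ], maxLag = maxLag)
  n <- length(k)
  ia <- max(1, 1 + lag):min(n, n + lag)
  ib <- ia - lag
  list(r = stats::cor(k[ia], trfWave@data[ch, ib]), lag = lag)
}

#' Replicate the four attention effects across seeded cohorts
#'
#' For each replicate seed, runs [cohortAnalysis()] restricted to the
#' peak-topography channel and records the group-level one-tailed t for the
#' four attention-decoding measures (ERP N1-P2, TRF N1-P2, theta-window
#' WPSS, SR accuracy).
#'
#' @param baseSpec a [CohortSpec-class]; each replicate reuses it with a
#'   derived seed
#' @param nReplicates number of replicate cohorts
#' @param seedBase base seed from which replicate seeds derive
#' @param verbose print progress
#' @return nReplicates x 4 matrix of t statistics (columns erpN1p2,
#'   trfN1p2, wpssTheta, srAccuracy)
#' @export
attentionEffectReplicates <- function(baseSpec, nReplicates = 10,
                                      seedBase = 100, verbose = FALSE) {
  peak <- which.max(baseSpec@topography)
  res <- matrix(NA_real_, nReplicates, 4,
                dimnames = list(NULL, c("erpN1p2", "trfN1p2", "wpssTheta",
                                        "srAccuracy")))
  for (i in seq_len(nReplicates)) {
    if (verbose) message(sprintf("replicate %d/%d", i, nReplicates))
    spec <- baseSpec
    spec@seed <- .subSeed(seedBase, i)
    an <- cohortAnalysis(spec, channels = peak, verbose = FALSE)
    res[i, ] <- vapply(c("erpN1p2", "trfN1p2", "wpssTheta", "srAccuracy"),
                       function(m) {
                         mm <- an$measures[[m]]
                         ch <- if (ncol(mm$attended) == 1) 1 else peak
                         pairedT(mm$attended[, ch], mm$ignored[, ch])$t
                       }, 0)
  }
  res
}
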