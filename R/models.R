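# Forward TRF estimation and backward stimulus reconstruction by ridge
# regression on lagged designs, with multi-lambda weight averaging and
# leave-one-trial-out evaluation.

#' Construct a lag grid
#'
#' Consecutive integer sample lags from \code{round(tauMinMs/1000 * fs)} to
#' \code{round(tauMaxMs/1000 * fs)}.  Forward models default to -250..700 ms,
#' backward models to 0..500 ms.
#'
#' @param tauMinMs,tauMaxMs lag range in ms
#' @param fs sampling rate, Hz
#' @return a [LagGrid-class]
#' @export
lagGrid <- function(tauMinMs, tauMaxMs, fs) {
  lags <- seq.int(round(tauMinMs / 1000 * fs), round(tauMaxMs / 1000 * fs))
  new("LagGrid", tauMinMs = tauMinMs, tauMaxMs = tauMaxMs, fs = fs,
      lags = as.integer(lags))
}

#' Lag times of a grid in ms
#' @param grid a [LagGrid-class]
#' @return numeric vector of lags in ms
#' @export
lagMs <- function(grid) grid@lags / grid@fs * 1000

#' Build a lagged design matrix
#'
#' Forward direction: column j at row t holds \code{source[t - lag_j]}
#' (single-channel stimulus, T x L).  Backward direction: source is a
#' channels-in-columns matrix and column (n-1)*L + j holds
#' \code{source[t + lag_j, n]} (T x N*L).  Out-of-range entries are zero.
#'
#' @param source numeric vector (forward) or T x N matrix (backward)
#' @param grid a [LagGrid-class]
#' @param direction "forward" or "backward"
#' @return the design matrix
#' @export
buildLaggedDesign <- function(source, grid, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  lags <- grid@lags
  shiftMat <- function(x, lagv) { # column j: y[t] = x[t - lagv[j]], zero-padded
    n <- length(x)
    idx <- outer(seq_len(n), as.integer(lagv), `-`)
    idx[idx < 1L | idx > n] <- n + 1L
    matrix(c(x, 0)[idx], n, length(lagv))
  }
  if (direction == "forward") {
    x <- as.numeric(source)
    if (length(x) < length(lags)) stop("buildLaggedDesign: source shorter than lag count")
    out <- shiftMat(x, lags)
  } else {
    m <- as.matrix(source)
    if (nrow(m) < length(lags)) stop("buildLaggedDesign: source shorter than lag count")
    out <- do.call(cbind, lapply(seq_len(ncol(m)), function(n)
      shiftMat(m[, n], -lags)))
  }
  out
}

#' Ridge regression solve
#'
#' Exact solution of \code{(X'X + lambda I) w = X'y} via a linear solve (no
#' explicit inverse).  \code{lambda = 0} requires a full-column-rank design.
#'
#' @param design T x P design matrix
#' @param target T-vector or T x K matrix of targets
#' @param lambda ridge penalty (>= 0)
#' @return P x K weight matrix (P-vector for vector targets)
#' @export
ridgeSolve <- function(design, target, lambda) {
  if (!is.finite(lambda) || lambda < 0) stop("ridgeSolve: lambda must be >= 0")
  A <- crossprod(design)
  diag(A) <- diag(A) + lambda
  b <- crossprod(design, target)
  w <- tryCatch(solve(A, b), error = function(e)
    stop("ridgeSolve: singular system (increase lambda): ", conditionMessage(e)))
  if (is.vector(target)) drop(w) else w
}

#' Default regularization grid
#'
#' 20 logarithmically spaced penalties between 1e-6 and 1e6.
#' @param n number of values
#' @param loExp,hiExp decade exponents of the range
#' @return numeric vector of penalties
#' @export
defaultLambdas <- function(n = 20, loExp = -6, hiExp = 6) {
  10^seq(loExp, hiExp, length.out = n)
}

# accumulate normal equations over trials (zero-padded lag windows at trial
# boundaries: no cross-trial leakage)
.accumulateNormal <- function(sources, targets, grid, direction) {
  XtX <- NULL; XtY <- NULL
  for (tr in seq_along(sources)) {
    X <- buildLaggedDesign(sources[[tr]], grid, direction)
    Y <- targets[[tr]]
    if (NROW(Y) != nrow(X)) stop("trial length mismatch between stimulus and response")
    XtX <- if (is.null(XtX)) crossprod(X) else XtX + crossprod(X)
    XtY <- if (is.null(XtY)) crossprod(X, Y) else XtY + crossprod(X, Y)
  }
  list(XtX = XtX, XtY = XtY)
}

# average of the ridge solutions over the penalty grid, via one symmetric
# eigendecomposition of X'X: w(lambda) = V diag(1/(d + lambda)) V' X'Y
.solveAveraged <- function(XtX, XtY, lambdas) {
  eig <- eigen(XtX, symmetric = TRUE)
  d <- pmax(eig$values, 0) # clamp tiny negative rounding
  B <- crossprod(eig$vectors, XtY)
  inv <- rowMeans(1 / outer(d, lambdas, `+`))
  eig$vectors %*% (B * inv)
}

#' Fit a forward temporal response function
#'
#' Trials are concatenated row-wise in the normal equations (one solve per
#' regularization value, all channels jointly since they share the stimulus
#' design), and the weight matrices from all penalties are averaged with
#' equal weights — no cross-validation.
#'
#' @param stimuli list (one per trial) of single-channel stimulus vectors or
#'   [OnsetEnvelope-class] objects
#' @param eeg list (one per trial) of [ContinuousRecording-class] or
#'   samples x channels matrices
#' @param grid a [LagGrid-class] (default -250..700 ms at the EEG rate)
#' @param lambdas penalties to average over (default [defaultLambdas()])
#' @return a forward [LinearModel-class] with lags x channels weights
#' @export
fitTrf <- function(stimuli, eeg, grid = NULL, lambdas = defaultLambdas()) {
  if (!length(stimuli) || length(stimuli) != length(eeg))
    stop("fitTrf: need matching, nonempty stimulus and EEG trial lists")
  sources <- lapply(stimuli, function(s) if (is(s, "OnsetEnvelope")) s@values else as.numeric(s))
  fs <- if (is(eeg[[1]], "ContinuousRecording")) eeg[[1]]@fs else NULL
  targets <- lapply(eeg, function(r) if (is(r, "ContinuousRecording")) t(r@data) else as.matrix(r))
  chans <- if (is(eeg[[1]], "ContinuousRecording")) eeg[[1]]@channels
           else sprintf("ch%02d", seq_len(ncol(targets[[1]])))
  grid <- grid %||% lagGrid(-250, 700, fs %||% stop("fitTrf: supply a LagGrid for matrix input"))
  acc <- .accumulateNormal(sources, targets, grid, "forward")
  W <- .solveAveraged(acc$XtX, acc$XtY, lambdas)
  new("LinearModel", direction = "forward", weights = W, lagGrid = grid,
      lambdas = lambdas, channels = chans,
      trials = seq_along(stimuli), postprocessed = FALSE)
}

#' Postprocess a forward TRF into a waveform
#'
#' 30 Hz zero-phase lowpass along the lag axis, baseline correction by the
#' mean over -50..0 ms, and trimming of the lag buffers so the waveform
#' spans -50..500 ms for direct ERP comparison.
#'
#' @param model a forward [LinearModel-class] (postprocessing twice is a
#'   state error)
#' @param spanMs output lag span, ms
#' @param baselineMs baseline window, ms
#' @param cutoffHz lowpass cutoff, Hz
#' @return a [Waveform-class] (channels x lags)
#' @export
postprocessTrf <- function(model, spanMs = c(-50, 500), baselineMs = c(-50, 0),
                           cutoffHz = 30) {
  stopifnot(is(model, "LinearModel"))
  if (model@direction != "forward") stop("postprocessTrf: forward models only")
  if (model@postprocessed) stop("postprocessTrf: model already postprocessed")
  fs <- model@lagGrid@fs
  bt <- signal::butter(3, cutoffHz / (fs / 2))
  W <- apply(model@weights, 2, function(col) signal::filtfilt(bt, col))
  lags <- model@lagGrid@lags
  base <- lags %in% .windowOffsets(baselineMs, fs)
  if (!any(base)) stop("postprocessTrf: baseline window outside the lag grid")
  W <- sweep(W, 2, colMeans(W[base, , drop = FALSE]))
  keep <- lags %in% .windowOffsets(spanMs, fs)
  new("Waveform", data = t(W[keep, , drop = FALSE]),
      timesMs = lags[keep] / fs * 1000, fs = fs, channels = model@channels)
}

#' Fit a backward stimulus-reconstruction decoder
#'
#' Same regularization approach as the forward model (one solve per penalty,
#' averaged) on the time-lagged multichannel EEG design.  Any channel
#' subset, including single channels, is supported.
#'
#' @param eeg list (one per trial) of [ContinuousRecording-class] or
#'   samples x channels matrices
#' @param stimuli list (one per trial) of stimulus vectors or
#'   [OnsetEnvelope-class] objects
#' @param grid a [LagGrid-class] (default 0..500 ms at the EEG rate)
#' @param lambdas penalties to average over
#' @param channels labels or indices of the channels to use (default all)
#' @return a backward [LinearModel-class]; column n of the weights holds the
#'   decoder block g(tau, n) of the n-th used channel
#' @export
fitDecoder <- function(eeg, stimuli, grid = NULL, lambdas = defaultLambdas(),
                       channels = NULL) {
  if (!length(eeg) || length(stimuli) != length(eeg))
    stop("fitDecoder: need matching, nonempty EEG and stimulus trial lists")
  fs <- if (is(eeg[[1]], "ContinuousRecording")) eeg[[1]]@fs else NULL
  grid <- grid %||% lagGrid(0, 500, fs %||% stop("fitDecoder: supply a LagGrid for matrix input"))
  prep <- .decoderSources(eeg, channels)
  sources <- prep$sources
  targets <- lapply(stimuli, function(s)
    if (is(s, "OnsetEnvelope")) s@values else as.numeric(s))
  acc <- .accumulateNormal(sources, targets, grid, "backward")
  w <- .solveAveraged(acc$XtX, acc$XtY, lambdas)
  L <- length(grid@lags)
  new("LinearModel", direction = "backward",
      weights = matrix(w, nrow = L, dimnames = NULL), lagGrid = grid,
      lambdas = lambdas, channels = prep$chans,
      trials = seq_along(eeg), postprocessed = FALSE)
}

.decoderSources <- function(eeg, channels) {
  asMat <- function(r) if (is(r, "ContinuousRecording")) t(r@data) else as.matrix(r)
  allCh <- if (is(eeg[[1]], "ContinuousRecording")) eeg[[1]]@channels
           else sprintf("ch%02d", seq_len(ncol(asMat(eeg[[1]]))))
  ix <- if (is.null(channels)) seq_along(allCh)
        else if (is.character(channels)) match(channels, allCh) else channels
  if (anyNA(ix)) stop("unknown channel(s) in decoder channel subset")
  list(sources = lapply(eeg, function(r) asMat(r)[, ix, drop = FALSE]),
       chans = allCh[ix])
}

#' Apply a backward decoder to EEG
#'
#' @param model a backward [LinearModel-class]
#' @param eeg a [ContinuousRecording-class] or samples x channels matrix with
#'   the same channel subset/order used for fitting
#' @return reconstructed stimulus vector
#' @export
applyDecoder <- function(model, eeg) {
  stopifnot(is(model, "LinearModel"), model@direction == "backward")
  m <- if (is(eeg, "ContinuousRecording")) {
    ix <- match(model@channels, eeg@channels)
    if (anyNA(ix)) stop("applyDecoder: decoder channels missing from recording")
    t(eeg@data[ix, , drop = FALSE])
  } else as.matrix(eeg)
  X <- buildLaggedDesign(m, model@lagGrid, "backward")
  drop(X %*% as.numeric(model@weights))
}

#' Leave-one-trial-out stimulus reconstruction
#'
#' One decoder is fitted per trial (each already averaged over the penalty
#' grid); for every fold the remaining trials' decoders are averaged with
#' equal weights and applied to the held-out trial, and accuracy is the
#' Pearson correlation between original and reconstructed stimulus.  The
#' alternative scheme that concatenates the training trials into a single
#' solve is available via \code{scheme = "concatenated"}.
#'
#' @param eeg,stimuli per-trial lists as in [fitDecoder()] (>= 3 trials)
#' @param grid a [LagGrid-class] (default 0..500 ms)
#' @param lambdas penalties to average over
#' @param channels channel subset (default all)
#' @param scheme "perTrialAverage" (default) or "concatenated"
#' @return list with \code{perTrialR} (one r per held-out trial) and
#'   \code{meanR}
#' @export
looReconstruction <- function(eeg, stimuli, grid = NULL,
                              lambdas = defaultLambdas(), channels = NULL,
                              scheme = c("perTrialAverage", "concatenated")) {
  scheme <- match.arg(scheme)
  nTrial <- length(eeg)
  if (nTrial < 3) stop("looReconstruction: need at least 3 trials")
  fs <- if (is(eeg[[1]], "ContinuousRecording")) eeg[[1]]@fs else NULL
  grid <- grid %||% lagGrid(0, 500, fs %||% stop("looReconstruction: supply a LagGrid"))
  prep <- .decoderSources(eeg, channels)
  sources <- prep$sources
  targets <- lapply(stimuli, function(s)
    if (is(s, "OnsetEnvelope")) s@values else as.numeric(s))
  L <- length(grid@lags)
  P <- L * ncol(sources[[1]])
  perTrial <- vector("list", nTrial) # per-trial XtX/XtY for both schemes
  for (tr in seq_len(nTrial)) {
    X <- buildLaggedDesign(sources[[tr]], grid, "backward")
    if (length(targets[[tr]]) != nrow(X)) stop("trial length mismatch")
    perTrial[[tr]] <- list(XtX = crossprod(X), Xty = crossprod(X, targets[[tr]]),
                           X = NULL)
  }
  trialW <- if (scheme == "perTrialAverage")
    lapply(perTrial, function(p) .solveAveraged(p$XtX, p$Xty, lambdas))
  weightsFor <- function(trainIdx) {
    if (scheme == "perTrialAverage") {
      Reduce(`+`, trialW[trainIdx]) / length(trainIdx)
    } else {
      XtX <- Reduce(`+`, lapply(perTrial[trainIdx], `[[`, "XtX"))
      Xty <- Reduce(`+`, lapply(perTrial[trainIdx], `[[`, "Xty"))
      .solveAveraged(XtX, Xty, lambdas)
    }
  }
  r <- numeric(nTrial)
  for (hold in seq_len(nTrial)) {
    g <- weightsFor(setdiff(seq_len(nTrial), hold))
    Xh <- buildLaggedDesign(sources[[hold]], grid, "backward")
    sHat <- drop(Xh %*% g)
    r[hold] <- stats::cor(sHat, targets[[hold]])
  }
  list(perTrialR = r, meanR = mean(r))
}
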