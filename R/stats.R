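# Group-level inference: one-tailed paired t-tests, cluster-mass permutation
# tests (1-D waveforms and 2-D time-frequency maps), attention-decoding
# t-statistic topographies, and t-map spatial correlations.

#' Paired t-test on attended/ignored value pairs
#'
#' Standard paired t on the differences with df = n - 1.  The one-tailed p
#' tests the "attended > ignored" direction.  Zero-variance differences are
#' a degenerate-test error.
#'
#' @param attended,ignored equal-length per-subject value vectors
#' @param tail "one_greater" (attended > ignored) or "two"
#' @return list with \code{t}, \code{df}, \code{p}
#' @export
pairedT <- function(attended, ignored, tail = c("one_greater", "two")) {
  tail <- match.arg(tail)
  if (length(attended) != length(ignored)) stop("pairedT: pair counts differ")
  if (length(attended) < 2) stop("pairedT: need at least 2 pairs")
  if (anyNA(attended) || anyNA(ignored)) stop("pairedT: missing entries")
  d <- attended - ignored
  s <- stats::sd(d)
  if (s == 0) stop("pairedT: zero-variance differences, test degenerate")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  p <- if (tail == "one_greater") stats::pt(t, n - 1, lower.tail = FALSE)
       else 2 * stats::pt(-abs(t), n - 1)
  list(t = t, df = n - 1, p = p)
}

# paired t maps for all columns of a subjects x cells difference matrix,
# under sign-flip vectors (rows of S in {-1, +1}^n)
.signFlipT <- function(D, S) {
  n <- nrow(D)
  ss <- colSums(D^2)
  M <- (S %*% D) / n
  V <- (matrix(ss, nrow(S), length(ss), byrow = TRUE) / n - M^2) * n / (n - 1)
  V[V < 0] <- 0
  M / sqrt(V / n)
}

#' Cluster-mass permutation test
#'
#' Two-tailed paired t per cell as the test statistic; cells with
#' \code{|t|} above the pre-clustering critical value form sign-homogeneous
#' connected clusters (temporal adjacency for 1-D waveforms, 4-neighbour
#' time-frequency adjacency for 2-D maps) scored by summed \code{|t|} mass.
#' The null distribution of the maximum cluster mass is built from random
#' within-subject condition sign flips (full enumeration when 2^n does not
#' exceed \code{nPerm}); a cluster is significant iff its mass exceeds the
#' (1 - pCluster) quantile of that null.
#'
#' @param attended,ignored subjects x cells matrices (1-D) or subjects x
#'   frequencies x times arrays (2-D), aligned
#' @param nPerm number of permutations (default 10000; fewer than 100 draws
#'   a warning)
#' @param pPre pre-clustering two-tailed threshold (default 0.01)
#' @param pCluster cluster-level threshold (default 0.05)
#' @param seed seed for the permutation draws
#' @return list with \code{tMap}, \code{threshold}, \code{labels} (cluster
#'   id per cell), \code{clusters} (data.frame id/sign/size/mass/p/
#'   significant), \code{nullMax}, \code{massCritical} and
#'   \code{significanceMask}
#' @export
clusterPermutation <- function(attended, ignored, nPerm = 10000, pPre = 0.01,
                               pCluster = 0.05, seed = 1) {
  if (!identical(dim(attended), dim(ignored)))
    stop("clusterPermutation: misaligned condition arrays")
  if (nPerm < 100) warning("clusterPermutation: nPerm < 100 gives a very coarse null")
  dm <- dim(attended)
  nSub <- dm[1]
  nr <- if (length(dm) == 3) dm[2] else 1L
  D <- matrix(attended - ignored, nSub)
  nCell <- ncol(D)
  df <- nSub - 1
  thr <- stats::qt(1 - pPre / 2, df)
  tObs <- drop(.signFlipT(D, matrix(1, 1, nSub)))
  tObs[!is.finite(tObs)] <- 0
  lab <- .labelClustersCpp(tObs, thr, nr)
  ids <- setdiff(sort(unique(lab)), 0L)
  # permutation null of the maximum cluster mass
  if (2^nSub <= nPerm) {
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), nSub)))
    nPerm <- nrow(S)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), nPerm * nSub, replace = TRUE), nPerm, nSub)
  }
  nullMax <- numeric(nPerm)
  block <- max(1L, floor(2e7 / nCell))
  for (st in seq(1, nPerm, by = block)) {
    en <- min(st + block - 1, nPerm)
    tP <- .signFlipT(D, S[st:en, , drop = FALSE])
    tP[!is.finite(tP)] <- 0
    nullMax[st:en] <- .permMaxClusterMassCpp(tP, thr, nr)
  }
  massCrit <- stats::quantile(nullMax, 1 - pCluster, names = FALSE)
  clusters <- data.frame(id = integer(0), sign = integer(0), size = integer(0),
                         mass = numeric(0), p = numeric(0), significant = logical(0))
  for (id in ids) {
    cells <- which(lab == id)
    mass <- sum(abs(tObs[cells]))
    clusters <- rbind(clusters, data.frame(
      id = id, sign = sign(tObs[cells[1]]), size = length(cells), mass = mass,
      p = (1 + sum(nullMax >= mass)) / (nPerm + 1),
      significant = mass > massCrit))
  }
  mask <- lab %in% clusters$id[clusters$significant]
  shape <- function(v) if (nr > 1) matrix(v, nr) else v
  list(tMap = shape(tObs), threshold = thr,
       labels = shape(lab), clusters = clusters, nullMax = nullMax,
       massCritical = massCrit, significanceMask = shape(mask))
}

#' Channel-wise attention-decoding t-statistics
#'
#' One-tailed (attended > ignored) paired t per channel for one decoding
#' measure.
#'
#' @param attended,ignored subjects x channels matrices of a measure
#' @return list with vectors \code{t} and \code{p} (one entry per channel)
#' @export
decodingTmap <- function(attended, ignored) {
  if (!identical(dim(attended), dim(ignored)))
    stop("decodingTmap: misaligned measure matrices")
  if (anyNA(attended) || anyNA(ignored)) stop("decodingTmap: incomplete measures")
  res <- lapply(seq_len(ncol(attended)), function(ch)
    pairedT(attended[, ch], ignored[, ch], "one_greater"))
  list(t = vapply(res, `[[`, 0, "t"), p = vapply(res, `[[`, 0, "p"))
}

#' Spatial correlation between two t-statistic maps
#'
#' Pearson correlation across channels with a two-sided p from the t
#' transform of r with df = channels - 2.
#'
#' @param mapA,mapB per-channel t-statistic vectors
#' @return list with \code{r2d}, \code{df}, \code{p}
#' @export
tmapCorrelation <- function(mapA, mapB) {
  r <- spatialCorrelation(mapA, mapB)
  df <- length(mapA) - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r2d = r, df = df, p = 2 * stats::pt(-abs(t), df))
}
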