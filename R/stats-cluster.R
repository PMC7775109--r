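# Cluster-based permutation test for paired ERP comparisons (clustering over
# time only; family-wise error control via the permutation distribution of
# the maximum cluster statistic).

# Same-sign suprathreshold runs of a t-series. Returns data.frame(start, end,
# stat) in sample indices (inclusive).
.findClusters <- function(tvals, threshold) {
  sig <- abs(tvals) > threshold
  if (!any(sig)) return(data.frame(start = integer(0), end = integer(0),
                                   stat = numeric(0)))
  lab <- cumsum(c(TRUE, diff(sign(tvals) * sig) != 0))
  lab[!sig] <- 0L
  keep <- split(which(sig), lab[sig])
  do.call(rbind, lapply(keep, function(idx) data.frame(
    start = min(idx), end = max(idx), stat = sum(tvals[idx]))))
}

#' Cluster-based permutation test for paired ERPs
#'
#' Pools the two paired condition ERPs, then repeatedly re-partitions by
#' randomly exchanging the condition labels within participants (the paired
#' analogue of partitioning the pooled set into two equal subsets). At each
#' time point a paired t-statistic is computed; points exceeding the
#' two-sided pointwise threshold are clustered by temporal adjacency
#' (same-sign runs), each cluster statistic is the sum of its t-values, and
#' the p-value of an observed cluster is the proportion of permutations
#' whose maximum |cluster statistic| is at least as large (ties counted,
#' conservative; floor 1/(nPermutations + 1)).
#'
#' @param erpA,erpB Participants x samples matrices, paired by row.
#' @param nPermutations Permutation count (default 2,000).
#' @param clusterAlpha Pointwise two-sided alpha forming clusters
#'   (default 0.05).
#' @param samplingRate Hz, used to express cluster extents in seconds.
#' @param timeOffset Time of the first sample in seconds (e.g. -0.1 for ERP
#'   windows with baseline).
#' @param seed Integer seed.
#' @return A [ClusterResult-class].
#' @export
clusterPermutationTest <- function(erpA, erpB, nPermutations = 2000L,
                                   clusterAlpha = 0.05, samplingRate = 128,
                                   timeOffset = 0, seed = 1L) {
  if (!identical(dim(erpA), dim(erpB)))
    stop("paired ERP matrices must have identical shapes")
  n <- nrow(erpA)
  if (n < 2) stop("need at least two participants")
  D <- erpA - erpB                       # n x T paired differences
  nT <- ncol(D)
  tcrit <- qt(1 - clusterAlpha / 2, df = n - 1)
  tSeries <- function(m, q) {
    # m: per-time mean of (signed) differences; q: per-time mean of squares
    v <- (q - m^2) * n / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  q <- colMeans(D^2)                     # invariant under sign flips
  tObs <- tSeries(colMeans(D), q)
  obs <- .findClusters(tObs, tcrit)
  nullMax <- withSeed(seed, {
    S <- matrix(sample(c(-1, 1), n * nPermutations, replace = TRUE),
                nrow = nPermutations)
    M <- (S %*% D) / n                   # nPermutations x T
    vapply(seq_len(nPermutations), function(b) {
      cl <- .findClusters(tSeries(M[b, ], q), tcrit)
      if (nrow(cl)) max(abs(cl$stat)) else 0
    }, numeric(1))
  })
  p <- if (nrow(obs))
    vapply(obs$stat, function(s)
      (sum(nullMax >= abs(s)) + 1) / (nPermutations + 1), numeric(1))
  else numeric(0)
  clustersDf <- if (nrow(obs)) data.frame(
    start = timeOffset + (obs$start - 1L) / samplingRate,
    end = timeOffset + (obs$end - 1L) / samplingRate,
    stat = obs$stat, p = pmin(p, 1))
  else data.frame(start = numeric(0), end = numeric(0), stat = numeric(0),
                  p = numeric(0))
  rownames(clustersDf) <- NULL
  new("ClusterResult", clusters = clustersDf,
      nPermutations = as.integer(nPermutations),
      clusterAlpha = clusterAlpha, tThreshold = tcrit, nullMax = nullMax)
}
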