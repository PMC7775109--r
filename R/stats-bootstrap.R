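# Bias-corrected and accelerated (BCa) bootstrap engine and the bootstrap
# tests built on it.
#
# Convention for resampling p-values (the "(N + 1)/10001" rule): N counts the
# resamples NOT supporting the alternative, so the strongest possible
# evidence yields the floor p = 1/(nResamples + 1) -- e.g. 1/10001, printed
# as p = 0.0001 at the default 10,000 resamples. Ties count against the
# alternative (conservative).

#' BCa bootstrap over participants
#'
#' Resamples participants with replacement `nResamples` times, applies
#' `statistic` to every resample, and computes the bias-corrected and
#' accelerated confidence interval: the bias term from the fraction of
#' resampled statistics below the point estimate, the acceleration from a
#' leave-one-out jackknife.
#'
#' @param values Per-participant values.
#' @param statistic Function of a numeric vector (default `mean`).
#' @param nResamples Resample count (default 10,000).
#' @param ciLevel Nominal CI coverage (default 0.95).
#' @param seed Integer seed.
#' @return List with `estimate`, `resamples` (numeric vector), `ci`
#'   (BCa interval), `z0`, `acceleration`, and `degenerate` (TRUE when
#'   n < 2, in which case the CI has zero width).
#' @export
bootstrapEngine <- function(values, statistic = mean, nResamples = 10000L,
                            ciLevel = 0.95, seed = 1L) {
  n <- length(values)
  est <- statistic(values)
  if (n < 2) {
    warning("fewer than 2 participants: bootstrap is degenerate")
    return(list(estimate = est, resamples = rep(est, nResamples),
                ci = c(est, est), z0 = 0, acceleration = 0,
                degenerate = TRUE))
  }
  res <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * nResamples, replace = TRUE),
                  nrow = nResamples)
    if (identical(statistic, mean)) rowMeans(matrix(values[idx],
                                                    nrow = nResamples))
    else apply(idx, 1, function(i) statistic(values[i]))
  })
  propBelow <- mean(res < est) + 0.5 * mean(res == est)
  z0 <- qnorm(min(max(propBelow, 1 / (nResamples + 1)),
                  1 - 1 / (nResamples + 1)))
  jack <- vapply(seq_len(n), function(i) statistic(values[-i]), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom > 0) sum((jm - jack)^3) / (6 * denom) else 0
  alpha <- (1 - ciLevel) / 2
  adj <- function(zalpha) pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  probs <- c(adj(qnorm(alpha)), adj(qnorm(1 - alpha)))
  ci <- unname(quantile(res, probs, type = 6))
  list(estimate = est, resamples = res, ci = ci, z0 = z0, acceleration = a,
       degenerate = FALSE)
}

#' One-sided bootstrap test of a spectral peak
#'
#' Tests whether the mean peak-minus-neighbours statistic across participants
#' is positive: participants are resampled with replacement and
#' `p = (N + 1)/(nResamples + 1)` where N is the number of resampled means
#' that are <= 0 (resamples contradicting the alternative).
#'
#' @param perParticipantValues Neighbour-corrected peak powers, one per
#'   participant.
#' @param nResamples Resample count (default 10,000).
#' @param ciLevel CI coverage for the accompanying BCa interval.
#' @param seed Integer seed.
#' @return A [StatResult-class] (one-sided).
#' @export
spectralPeakTest <- function(perParticipantValues, nResamples = 10000L,
                             ciLevel = 0.95, seed = 1L) {
  bt <- bootstrapEngine(perParticipantValues, mean, nResamples, ciLevel, seed)
  nAgainst <- sum(bt$resamples <= 0)
  p <- (nAgainst + 1) / (nResamples + 1)
  new("StatResult", method = "spectral_peak_bootstrap",
      statistic = bt$estimate, pValue = min(p, 1),
      nResamples = as.integer(nResamples), ci = bt$ci, ciLevel = ciLevel,
      sidedness = "one-sided", seed = as.integer(seed),
      extra = list(resamples = bt$resamples))
}

#' Two-sided paired bootstrap test of a power difference
#'
#' For paired per-participant neighbour-corrected powers, resamples
#' participants and computes the mean paired difference per resample;
#' `p = (2 * N + 1)/(nResamples + 1)` where N is the count in the minority
#' tail (two-sided), so swapping the conditions leaves p unchanged.
#'
#' @param condA,condB Paired per-participant values (equal length).
#' @param nResamples Resample count (default 10,000).
#' @param ciLevel CI coverage.
#' @param seed Integer seed.
#' @return A [StatResult-class] (two-sided); statistic is `mean(condA - condB)`.
#' @export
powerDifferenceTest <- function(condA, condB, nResamples = 10000L,
                                ciLevel = 0.95, seed = 1L) {
  if (length(condA) != length(condB))
    stop("paired conditions must have equal length")
  d <- condA - condB
  bt <- bootstrapEngine(d, mean, nResamples, ciLevel, seed)
  nMinority <- min(sum(bt$resamples <= 0), sum(bt$resamples >= 0))
  p <- (2 * nMinority + 1) / (nResamples + 1)
  new("StatResult", method = "power_difference_bootstrap",
      statistic = bt$estimate, pValue = min(p, 1),
      nResamples = as.integer(nResamples), ci = bt$ci, ciLevel = ciLevel,
      sidedness = "two-sided", seed = as.integer(seed),
      extra = list(resamples = bt$resamples))
}

#' Two-sided bootstrap comparison across independent experiments
#'
#' Bootstraps the sample mean of each group independently; the significance
#' level v is the (doubled) percentile position of zero in the resampled
#' distribution of the between-group mean difference. When one group's
#' sampling variability vanishes this reduces to asking whether that group's
#' observed mean exceeds the 100v/2 (or falls below the v/2) percentile of
#' the other group's resampled-mean distribution; unlike that one-group
#' rule, the difference distribution accounts for both groups' variability
#' and keeps the nominal type-I error (see the methods vignette).
#'
#' @param valuesA,valuesB Independent per-participant values.
#' @param nResamples Resample count (default 10,000).
#' @param seed Integer seed.
#' @return A [StatResult-class] (two-sided); statistic is
#'   `mean(valuesA) - mean(valuesB)`.
#' @export
crossExperimentTest <- function(valuesA, valuesB, nResamples = 10000L,
                                seed = 1L) {
  seeds <- deriveSeeds(seed, 2)
  btA <- bootstrapEngine(valuesA, mean, nResamples, seed = seeds[1])
  btB <- bootstrapEngine(valuesB, mean, nResamples, seed = seeds[2])
  dd <- btA$resamples - btB$resamples
  lo <- (sum(dd <= 0) + 1) / (nResamples + 1)
  hi <- (sum(dd >= 0) + 1) / (nResamples + 1)
  p <- min(1, 2 * min(lo, hi))
  new("StatResult", method = "cross_experiment_bootstrap",
      statistic = btA$estimate - btB$estimate, pValue = p,
      nResamples = as.integer(nResamples), sidedness = "two-sided",
      seed = as.integer(seed),
      extra = list(resamplesA = btA$resamples, resamplesB = btB$resamples,
                   resampledDifference = dd))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction via [stats::p.adjust()]; adjusted
#' values are monotone in the input ranks and never below the raw p-values.
#'
#' @param pValues p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
fdrAdjust <- function(pValues) {
  if (!length(pValues)) return(numeric(0))
  if (any(!is.finite(pValues)) || any(pValues <= 0) || any(pValues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Paired effect size and achieved power
#'
#' Cohen's d for paired differences, `d = mean(x - y) / sd(x - y)`, with the
#' achieved power of the corresponding paired (one-sample) t-test computed
#' from the noncentral t distribution.
#'
#' @param valuesTarget,valuesReference Paired samples (e.g. power at the
#'   target frequency vs the neighbour-bin average), length >= 2.
#' @param sigLevel Test level (default 0.05, two-sided).
#' @return List with `d`, `power`, `n`, `tStatistic` and `pValue` (paired
#'   t-test, two-sided).
#' @export
pairedEffectSize <- function(valuesTarget, valuesReference, sigLevel = 0.05) {
  if (length(valuesTarget) != length(valuesReference))
    stop("samples must be paired")
  n <- length(valuesTarget)
  if (n < 2) stop("need at least two pairs")
  d <- valuesTarget - valuesReference
  s <- sd(d)
  if (s == 0) stop("paired differences have zero variance; d is undefined")
  dz <- mean(d) / s
  pw <- power.t.test(n = n, delta = abs(mean(d)), sd = s,
                     sig.level = sigLevel, type = "one.sample",
                     alternative = "two.sided")$power
  tt <- t.test(valuesTarget, valuesReference, paired = TRUE)
  list(d = dz, power = pw, n = n,
       tStatistic = unname(tt$statistic), pValue = tt$p.value)
}
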