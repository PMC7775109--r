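# Circular statistics: bootstrap distributions of circular means, shortest
# covering-arc confidence intervals, and the inter-participant phase
# coherence test.

#' Bootstrap distribution of the circular mean
#'
#' Resamples participants' angles with replacement and computes the circular
#' mean of each resample; the feedstock for [phaseDifferenceCI()].
#'
#' @param anglesDeg Per-participant angles in degrees.
#' @param nResamples Resample count (default 10,000).
#' @param seed Integer seed.
#' @return Numeric vector of resampled circular means (degrees).
#' @export
bootstrapCircularMean <- function(anglesDeg, nResamples = 10000L, seed = 1L) {
  n <- length(anglesDeg)
  withSeed(seed, {
    idx <- matrix(sample.int(n, n * nResamples, replace = TRUE),
                  nrow = nResamples)
    z <- matrix(exp(1i * anglesDeg[idx] * pi / 180), nrow = nResamples)
    wrapDegrees(Arg(rowSums(z)) * 180 / pi)
  })
}

#' Shortest covering-arc confidence interval for a phase
#'
#' The V% confidence interval is the smallest arc that covers V% of the
#' resampled angles. Returned as `c(lo, hi)` in degrees with
#' `lo <= hi <= lo + 360`; the arc runs counter-clockwise from `lo` to `hi`
#' (an interval straddling 180 has `hi > 180`).
#'
#' @param resampledDeg Resampled angles in degrees (e.g. from
#'   [bootstrapCircularMean()]).
#' @param coverage Coverage V in percent, in (0, 100].
#' @return Numeric `c(lo, hi)` with attribute `"width"` (arc width, degrees).
#' @export
phaseDifferenceCI <- function(resampledDeg, coverage = 95) {
  if (coverage <= 0 || coverage > 100)
    stop("coverage must be in (0, 100]")
  x <- sort(resampledDeg %% 360)
  n <- length(x)
  m <- ceiling(coverage / 100 * n)
  if (m >= n) {
    # full sample: smallest arc containing all points
    gaps <- diff(c(x, x[1] + 360))
    if (max(gaps) <= 0 || n == 1) {
      out <- wrapDegrees(c(x[1], x[1]))
      attr(out, "width") <- 0
      return(out)
    }
    k <- which.max(gaps)
    lo <- x[(k %% n) + 1L]
    hi <- x[k] + if (k %% n + 1L > k) 0 else 360
    width <- 360 - max(gaps)
    if (width >= 360 - 1e-9) { lo <- -180; hi <- 180; width <- 360 }
    out <- c(wrapDegrees(lo), wrapDegrees(lo) + width)
    attr(out, "width") <- width
    return(out)
  }
  ext <- c(x, x + 360)
  widths <- ext[seq_len(n) + m - 1L] - x
  k <- which.min(widths)
  lo <- wrapDegrees(x[k])
  out <- c(lo, lo + widths[k])
  attr(out, "width") <- widths[k]
  out
}

# Mean resultant length of angles in degrees.
.resultantLength <- function(anglesDeg) {
  Mod(mean(exp(1i * anglesDeg * pi / 180)))
}

#' Inter-participant phase coherence test
#'
#' The statistic is the mean resultant length of the per-participant phases.
#' The null distribution is generated by drawing the same number of phases
#' uniformly on the circle `nNull` times; `p = (N + 1)/(nNull + 1)` where N
#' is the number of null coherence values at or above the observed one.
#'
#' @param phasesDeg Per-participant phases in degrees (>= 2).
#' @param nNull Null draws (default 10,000).
#' @param seed Integer seed.
#' @return A [StatResult-class] (one-sided).
#' @export
phaseCoherenceTest <- function(phasesDeg, nNull = 10000L, seed = 1L) {
  n <- length(phasesDeg)
  if (n < 2) stop("need at least two phases")
  obs <- .resultantLength(phasesDeg)
  nullR <- withSeed(seed, {
    u <- matrix(runif(n * nNull, -pi, pi), nrow = nNull)
    Mod(rowMeans(exp(1i * u)))
  })
  p <- (sum(nullR >= obs) + 1) / (nNull + 1)
  new("StatResult", method = "phase_coherence", statistic = obs,
      pValue = min(p, 1), nResamples = as.integer(nNull),
      sidedness = "one-sided", seed = as.integer(seed),
      extra = list(nullDistribution = nullR))
}
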