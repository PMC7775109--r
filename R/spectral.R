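# Coherent trial averaging, DFT, neighbour-bin peak statistics and circular
# phase measures.

#' Coherent trial average and one-sided spectrum
#'
#' Averages the kept trials in the time domain first (coherent averaging, so
#' phase-inconsistent activity cancels), then applies the DFT per channel
#' with no taper. Coefficients are normalised by the sample count, so a
#' unit-amplitude cosine appears with magnitude 1/2 at its bin and its cosine
#' phase; the bin spacing is `1/epochDuration` Hz (1/7 Hz for 7-s trials).
#'
#' @param epochs An [EpochedResponse-class] with at least one kept trial.
#' @return A [FreqSpectrum-class].
#' @export
averageAndSpectrum <- function(epochs) {
  nTr <- dim(epochs@data)[1]
  if (nTr < 1) stop("no kept trials to average")
  avg <- apply(epochs@data, c(2, 3), mean)      # channels x samples
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1)
  n <- ncol(avg)
  nBins <- n %/% 2L + 1L
  coef <- t(apply(avg, 1, function(row) fft(row)[seq_len(nBins)] / n))
  if (nrow(avg) == 1L) coef <- matrix(coef, nrow = 1)
  new("FreqSpectrum", coefficients = coef,
      frequencies = (seq_len(nBins) - 1L) / epochs@epochDuration,
      epochDuration = epochs@epochDuration, nTrialsAveraged = as.integer(nTr),
      channelLabels = epochs@channelLabels)
}

#' Spectral power of a spectrum
#'
#' Power is the squared magnitude of the normalised Fourier coefficients
#' (no one-sided doubling); all pipeline comparisons are relative, so the
#' normalisation convention cancels.
#'
#' @param spectrum A [FreqSpectrum-class].
#' @return Numeric matrix, channels x bins.
#' @export
spectrumPower <- function(spectrum) {
  p <- Mod(spectrum@coefficients)^2
  dimnames(p) <- list(spectrum@channelLabels, NULL)
  p
}

.binIndex <- function(spectrum, f, tol = 1e-6) {
  i <- which.min(abs(spectrum@frequencies - f))
  if (abs(spectrum@frequencies[i] - f) > tol)
    stop(sprintf("frequency %g Hz is off the bin grid (nearest bin %.6f Hz)",
                 f, spectrum@frequencies[i]))
  i
}

#' Peak-minus-neighbours power statistic
#'
#' The frequency-tagging peak measure: power at the target bin minus the mean
#' power of the `nSide` neighbouring bins on each side (four bins in total by
#' default), computed per channel and averaged over channels. Off-grid target
#' frequencies are an error (silent bin mismatch prevention).
#'
#' @param spectrum A [FreqSpectrum-class].
#' @param fTarget Target frequency in Hz; must sit on the bin grid.
#' @param nSide Neighbour bins per side (default 2).
#' @return List with `perChannel` (named numeric) and `average` (scalar);
#'   also `neighborFrequencies` for audit.
#' @export
peakMinusNeighbors <- function(spectrum, fTarget, nSide = 2L) {
  i <- .binIndex(spectrum, fTarget)
  nb <- c(i - seq_len(nSide), i + seq_len(nSide))
  if (any(nb < 1L) || any(nb > length(spectrum@frequencies)))
    stop("not enough neighbour bins around the target frequency")
  p <- spectrumPower(spectrum)
  stat <- p[, i] - rowMeans(p[, nb, drop = FALSE])
  names(stat) <- spectrum@channelLabels
  list(perChannel = stat, average = mean(stat),
       neighborFrequencies = spectrum@frequencies[nb])
}

#' Circular mean of angles
#'
#' Direction of the mean resultant vector; the only valid average for
#' phases. When the resultant length falls below `tol` (e.g. antipodal
#' angles) the mean direction is flagged undefined.
#'
#' @param anglesDeg Angles in degrees.
#' @param weights Optional non-negative weights.
#' @param tol Resultant-length tolerance below which the mean is undefined.
#' @return A [PhaseStat-class].
#' @examples
#' meanAngle(circularMean(c(10, 20, 30)))  # 20
#' @export
circularMean <- function(anglesDeg, weights = NULL, tol = 1e-12) {
  if (!length(anglesDeg)) stop("need at least one angle")
  if (is.null(weights)) weights <- rep(1, length(anglesDeg))
  z <- sum(weights * exp(1i * anglesDeg * pi / 180)) / sum(weights)
  R <- Mod(z)
  defined <- R >= tol
  new("PhaseStat",
      meanAngle = if (defined) wrapDegrees(Arg(z) * 180 / pi) else NA_real_,
      resultantLength = R, n = length(anglesDeg), defined = defined)
}

#' Phase difference between two conditions at a target frequency
#'
#' Computes the wrapped per-channel phase difference `arg(a) - arg(b)` at the
#' target bin. Given lists of spectra (one per participant, same order in
#' both conditions), the difference is first averaged over participants per
#' channel by the circular mean; the grand summary is the circular mean over
#' channels.
#'
#' @param specA,specB [FreqSpectrum-class] objects or lists thereof
#'   (participants), on identical bin grids.
#' @param f Target frequency in Hz.
#' @return List with `perChannel` (degrees, named) and `grand`
#'   (a [PhaseStat-class]).
#' @export
conditionPhaseDifference <- function(specA, specB, f) {
  if (is(specA, "FreqSpectrum")) specA <- list(specA)
  if (is(specB, "FreqSpectrum")) specB <- list(specB)
  if (length(specA) != length(specB))
    stop("condition lists must pair participants")
  ref <- specA[[1]]
  diffs <- vapply(seq_along(specA), function(p) {
    a <- specA[[p]]; b <- specB[[p]]
    if (!isTRUE(all.equal(a@frequencies, b@frequencies)) ||
        !isTRUE(all.equal(a@frequencies, ref@frequencies)))
      stop("spectra are on different bin grids")
    i <- .binIndex(a, f)
    wrapDegrees((Arg(a@coefficients[, i]) - Arg(b@coefficients[, i])) *
                180 / pi)
  }, numeric(nrow(ref@coefficients)))
  if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = 1)
  perChannel <- apply(diffs, 1, function(d) meanAngle(circularMean(d)))
  names(perChannel) <- ref@channelLabels
  list(perChannel = perChannel, grand = circularMean(perChannel))
}

#' Parseval consistency check
#'
#' Total two-sided power of the trial-averaged waveform reconstructed from
#' the one-sided coefficients, compared with the time-domain mean square.
#' Used as a normalisation audit.
#'
#' @param epochs An [EpochedResponse-class].
#' @return List with `timeDomain` and `freqDomain` mean-square energies.
#' @export
parsevalCheck <- function(epochs) {
  avg <- apply(epochs@data, c(2, 3), mean)
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1)
  n <- ncol(avg)
  spec <- averageAndSpectrum(epochs)
  p <- Mod(spec@coefficients)^2
  even <- n %% 2L == 0L
  inner <- 2:(ncol(p) - if (even) 1L else 0L)
  fd <- p[, 1] + 2 * rowSums(p[, inner, drop = FALSE]) +
    if (even) p[, ncol(p)] else 0
  list(timeDomain = rowMeans(avg^2), freqDomain = fd)
}
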