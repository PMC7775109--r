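# Linear-phase FIR band-pass design and zero-delay application.

#' Design the linear-phase band-pass FIR filter
#'
#' Hamming-windowed-sinc band-pass with `windowDuration * samplingRate + 1`
#' symmetric taps (odd count, so the N/2 group delay is an integer number of
#' samples). The windowed-sinc construction attenuates by -6 dB (gain 0.5)
#' exactly at the cut-off frequencies.
#'
#' @param samplingRate Hz.
#' @param low,high Band edges in Hz (defaults 0.8 and 30).
#' @param windowDuration Design window length in seconds (default 6).
#' @return A [FilterSpec-class].
#' @examples
#' spec <- designBandpassFIR(128)
#' length(spec@taps)  # 6 * 128 + 1 = 769
#' @export
designBandpassFIR <- function(samplingRate, low = 0.8, high = 30,
                              windowDuration = 6) {
  if (!(low > 0 && low < high && high < samplingRate / 2))
    stop("need 0 < low < high < samplingRate / 2")
  if (windowDuration < 2 / low)
    stop("window too short to resolve the low cut-off: need at least ",
         sprintf("%.2f s for %g Hz", 2 / low, low))
  N <- as.integer(round(windowDuration * samplingRate))
  if (N %% 2L == 1L) N <- N + 1L
  k <- seq(-N / 2, N / 2)
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  ideal <- (2 * high / samplingRate) * sinc(2 * high * k / samplingRate) -
           (2 * low / samplingRate) * sinc(2 * low * k / samplingRate)
  m <- seq(0, N)
  hamming <- 0.54 - 0.46 * cos(2 * pi * m / N)
  taps <- ideal * hamming
  new("FilterSpec", taps = taps, N = N, band = c(low, high),
      windowDuration = windowDuration, samplingRate = samplingRate)
}

#' Frequency response of a FIR filter
#'
#' @param spec A [FilterSpec-class].
#' @param freqs Frequencies in Hz.
#' @return Complex gains at `freqs`.
#' @export
filterResponse <- function(spec, freqs) {
  vapply(freqs, function(f) {
    sum(spec@taps * exp(-2i * pi * f * seq(0, spec@N) / spec@samplingRate))
  }, complex(1))
}

# FFT convolution of each row of a matrix with a tap vector; returns the
# causal output (same length as input), i.e. y[k] = sum_j h[j] x[k - j].
.filterRows <- function(x, taps) {
  n <- ncol(x)
  nf <- stats::nextn(n + length(taps) - 1L, 2)
  H <- fft(c(taps, numeric(nf - length(taps))))
  t(apply(x, 1, function(row) {
    y <- Re(fft(fft(c(row, numeric(nf - n))) * H, inverse = TRUE)) / nf
    y[seq_len(n)]
  }))
}

#' Apply a FIR filter with group-delay compensation
#'
#' Filters every channel and removes the first `N/2` samples of the output so
#' the result has zero group delay (an in-band impulse stays at its input
#' sample). The trailing `N/2` samples are also dropped, so every retained
#' sample is fully filtered; the output is `N/2` samples shorter than the
#' input.
#'
#' @param recording An [EEGRecording-class].
#' @param spec A [FilterSpec-class] designed at the recording's sampling rate.
#' @return The filtered [EEGRecording-class].
#' @export
applyFilterCompensated <- function(recording, spec) {
  if (abs(spec@samplingRate - recording@samplingRate) > 1e-9)
    stop("filter was designed for a different sampling rate")
  n <- ncol(recording@data)
  if (n <= spec@N + 1L)
    stop("recording shorter than the filter: ", n, " samples <= ",
         spec@N + 1L, " taps")
  half <- spec@N %/% 2L
  y <- .filterRows(recording@data, spec@taps)
  keep <- seq.int(half + 1L, n - half)
  out <- recording
  out@data <- y[, keep, drop = FALSE]
  if (length(recording@mask))
    out@mask <- recording@mask[, keep, drop = FALSE]
  out@provenance <- c(recording@provenance, "bandpass")
  out
}

#' Downsample a recording
#'
#' Anti-alias low-pass filters (windowed-sinc FIR with cut-off at 80% of the
#' target Nyquist, delay-compensated) and keeps every `factor`-th sample.
#' Event times in seconds are unchanged by construction. Requires the
#' original rate to be an integer multiple of `targetRate`.
#'
#' @param recording An [EEGRecording-class].
#' @param targetRate Target sampling rate in Hz (default 128).
#' @return The downsampled [EEGRecording-class].
#' @export
downsampleRecording <- function(recording, targetRate = 128) {
  fs <- recording@samplingRate
  if (targetRate > fs) stop("target rate exceeds the original rate")
  if (targetRate == fs) {
    out <- recording
    out@provenance <- c(recording@provenance, "downsample")
    return(out)
  }
  factor <- fs / targetRate
  if (abs(factor - round(factor)) > 1e-9)
    stop("original rate must be an integer multiple of the target rate")
  factor <- as.integer(round(factor))
  cutoff <- 0.8 * targetRate / 2
  L <- 16L * factor
  k <- seq(-L / 2, L / 2)
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  taps <- (2 * cutoff / fs) * sinc(2 * cutoff * k / fs) *
    (0.54 - 0.46 * cos(2 * pi * seq(0, L) / L))
  n <- ncol(recording@data)
  # zero-pad so delay compensation keeps the exact 1/factor length ratio
  padded <- cbind(recording@data, matrix(0, nrow(recording@data), L / 2))
  y <- .filterRows(padded, taps)
  aligned <- y[, seq.int(L / 2 + 1L, n + L / 2), drop = FALSE]
  out <- recording
  out@data <- aligned[, seq.int(1L, ncol(aligned), by = factor), drop = FALSE]
  out@samplingRate <- targetRate
  out@mask <- matrix(logical(0), 0, 0)
  out@provenance <- c(recording@provenance, "downsample")
  out
}
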