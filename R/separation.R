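# Separation of word-locked and AM-locked response components by condition
# averaging, topography normalisation, and sigma1/sigma2 ERP extraction for
# disyllabic words.
#
# Word onsets are aligned between the sigma1- and sigma2-amplified
# conditions, while the amplified-syllable train is offset by 250 ms. At
# 2 Hz a 250-ms offset is a 180-degree phase shift, so the plain average of
# the two condition responses cancels the AM-locked 2-Hz component (word
# response), and averaging after delaying the sigma1-condition response by
# 250 ms cancels the word-locked 2-Hz component (AM response).

.asWaveform <- function(x) {
  if (is(x, "EpochedResponse")) {
    w <- apply(x@data, c(2, 3), mean)
    if (is.null(dim(w))) w <- matrix(w, nrow = 1)
    w
  } else if (is.matrix(x)) x
  else matrix(x, nrow = 1)
}

#' Word response: average the two AM-condition responses
#'
#' Elementwise mean of the sigma1- and sigma2-amplified condition waveforms.
#' The AM-locked 2-Hz component is antiphase between conditions and cancels;
#' the word-locked component is preserved.
#'
#' @param respSigma1,respSigma2 Trial-averaged condition waveforms: matrices
#'   (channels x samples) or [EpochedResponse-class] objects of equal shape.
#' @return Channels x samples matrix tagged `"word_response"`.
#' @export
wordAverage <- function(respSigma1, respSigma2) {
  a <- .asWaveform(respSigma1); b <- .asWaveform(respSigma2)
  if (!identical(dim(a), dim(b))) stop("condition waveforms differ in shape")
  out <- (a + b) / 2
  attr(out, "component") <- "word_response"
  out
}

#' AM response: average after realigning by the 250-ms condition offset
#'
#' Delays the sigma1-condition waveform by `delay` seconds (so the amplified
#' syllables align between conditions) and averages with the
#' sigma2-condition waveform. The word-locked 2-Hz component is then
#' antiphase and cancels; the AM-locked component is preserved. The delay is
#' applied as a circular shift within the trial: trials are phase-continuous
#' concatenations whose excised spans are multiples of the 0.5-s word
#' period, so the wrap preserves exact 2-Hz antiphase cancellation. A delay
#' that is not an integer number of samples is rejected rather than
#' interpolated.
#'
#' @param respSigma1,respSigma2 As in [wordAverage()].
#' @param delay Realignment delay in seconds (default 0.25; 0 reduces to
#'   [wordAverage()]).
#' @param samplingRate Hz of the waveforms.
#' @return Channels x samples matrix tagged `"am_response"`.
#' @export
amAverage <- function(respSigma1, respSigma2, delay = 0.25,
                      samplingRate = 128) {
  a <- .asWaveform(respSigma1); b <- .asWaveform(respSigma2)
  if (!identical(dim(a), dim(b))) stop("condition waveforms differ in shape")
  dSamp <- delay * samplingRate
  if (abs(dSamp - round(dSamp)) > 1e-9)
    stop("delay must be an integer number of samples at this rate; ",
         "got ", dSamp, " samples")
  dSamp <- as.integer(round(dSamp)) %% ncol(a)
  shifted <- if (dSamp == 0) a else
    a[, c((ncol(a) - dSamp + 1L):ncol(a), 1L:(ncol(a) - dSamp)), drop = FALSE]
  out <- (shifted + b) / 2
  attr(out, "component") <- "am_response"
  out
}

#' Normalise a topography to unit maximum
#'
#' @param powerMap Per-channel power (named numeric), maximum must be > 0.
#' @return `powerMap / max(powerMap)`; scale-invariant, output maximum 1.
#' @export
normalizeTopography <- function(powerMap) {
  m <- max(powerMap)
  if (!is.finite(m) || m <= 0)
    stop("topography maximum must be positive to normalise")
  powerMap / m
}

#' Spectrum of a separated component waveform
#'
#' Helper that wraps a channels x samples waveform (e.g. the output of
#' [wordAverage()]) into a trial grid of `epochDuration` and computes its
#' spectrum, for reuse of the spectral statistics.
#'
#' @param waveform Channels x samples matrix.
#' @param samplingRate Hz.
#' @param epochDuration Seconds per trial (default 7).
#' @param channelLabels Optional channel names.
#' @return A [FreqSpectrum-class].
#' @export
waveformSpectrum <- function(waveform, samplingRate, epochDuration = 7,
                             channelLabels = NULL) {
  nPer <- as.integer(round(epochDuration * samplingRate))
  nTr <- ncol(waveform) %/% nPer
  if (nTr < 1) stop("waveform shorter than one epoch")
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(waveform)))
  dat <- array(0, dim = c(nTr, nrow(waveform), nPer))
  for (t in seq_len(nTr))
    dat[t, , ] <- waveform[, ((t - 1L) * nPer + 1L):(t * nPer)]
  epochs <- new("EpochedResponse", data = dat, samplingRate = samplingRate,
                epochDuration = epochDuration, channelLabels = channelLabels,
                keptTrials = seq_len(nTr),
                rejectionLog = data.frame(trial = integer(0),
                                          reason = character(0)),
                trialMasked = rep(FALSE, nTr), provenance = "waveform")
  averageAndSpectrum(epochs)
}

#' Sigma1/sigma2 ERPs for disyllabic words
#'
#' Extracts the responses to the first (sigma1) and second (sigma2) syllables
#' of every disyllabic word over a `[-0.1, 0.75]` s window relative to
#' syllable onset, baseline-corrects each epoch by subtracting the mean over
#' the 100-ms pre-onset window, and averages across words. Monosyllabic
#' words are not analysed. Words whose epochs overlap masked samples or run
#' outside the recording are excluded.
#'
#' @param recording A preprocessed [EEGRecording-class].
#' @param timeline The timed [SyllableTimeline-class].
#' @param window Epoch window in seconds relative to onset.
#' @return An [ERPPair-class].
#' @export
disyllabicERPs <- function(recording, timeline, window = c(-0.1, 0.75)) {
  fs <- recording@samplingRate
  ev <- timeline@events
  eeg <- recording@channelRoles == "eeg"
  dat <- recording@data[eeg, , drop = FALSE]
  labels <- recording@channelLabels[eeg]
  mask <- if (length(recording@mask))
    recording@mask[eeg, , drop = FALSE] else NULL
  n <- ncol(dat)
  i0 <- timeToSample(window[1], fs)
  i1 <- timeToSample(window[2], fs) - 1L
  nSamp <- i1 - i0 + 1L
  baseCols <- seq_len(-i0)  # samples before onset
  words <- split(seq_len(nrow(ev)), ev$wordId)
  words <- words[vapply(words, length, 1L) == 2L]
  if (!length(words)) stop("timeline contains no disyllabic words")
  sum1 <- matrix(0, sum(eeg), nSamp)
  sum2 <- matrix(0, sum(eeg), nSamp)
  nW <- 0L
  epochAt <- function(onset) {
    c0 <- timeToSample(onset, fs) + i0
    if (c0 < 0 || c0 + nSamp > n) return(NULL)
    cols <- (c0 + 1L):(c0 + nSamp)
    if (!is.null(mask) && any(mask[, cols])) return(NULL)
    e <- dat[, cols, drop = FALSE]
    e - rowMeans(e[, baseCols, drop = FALSE])
  }
  for (w in words) {
    e1 <- epochAt(ev$onset[w[1]])
    e2 <- epochAt(ev$onset[w[2]])
    if (is.null(e1) || is.null(e2)) next
    sum1 <- sum1 + e1; sum2 <- sum2 + e2; nW <- nW + 1L
  }
  if (nW == 0L) stop("no disyllabic word survived epoch extraction")
  new("ERPPair", erpS1 = sum1 / nW, erpS2 = sum2 / nW,
      time = (i0:i1) / fs, samplingRate = fs, channelLabels = labels,
      nWords = nW)
}
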