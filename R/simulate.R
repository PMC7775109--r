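# Forward simulation of multichannel EEG with word-, syllable- and AM-locked
# evoked components, 1/f^alpha background noise and ocular artifacts.
#
# The response model is additive and linear: each component is an impulse
# train at its event onsets convolved with its kernel, scaled by its
# amplitude, and spread over channels by its topography. Because the
# word-locked component depends only on word onsets, sigma1- and
# sigma2-amplified variants of the same text produce sample-identical
# word-locked responses, while the AM-locked response in the sigma2 condition
# is the sigma1-condition response delayed by exactly 0.250 s.

#' Build a simulation configuration
#'
#' @param samplingRate Hz. 2048 exercises the full recording chain
#'   (downsampling included); 128 is the fast mode used throughout analyses.
#' @param channels Scalp channels to simulate; HEOG, VEOG, M1, M2 are always
#'   appended.
#' @param amplitudeWord,amplitudeSyllable,amplitudeAm Component amplitudes in
#'   microvolts (0 disables a component).
#' @param kernelWord,kernelSyllable,kernelAm [ErpKernel-class] ground truths;
#'   defaults are gamma lobes with latencies 180/90/120 ms.
#' @param topographyWord,topographySyllable,topographyAm Named weight maps
#'   over `channels` with max |weight| 1; defaults: centro-frontal for the
#'   word- and syllable-locked components, temporal for the AM-locked one.
#' @param noiseSd Background 1/f^alpha noise sd per channel (microvolts).
#' @param noiseExponent Spectral exponent alpha (default 1).
#' @param eogSd Ocular (random-walk) component sd in the EOG channels.
#' @param eogGainV,eogGainH Per-channel leakage of the vertical/horizontal
#'   ocular components into scalp channels.
#' @param artifactRate Rate (events/s) of large transient artifacts; 0 (the
#'   default) simulates a clean recording.
#' @param artifactAmplitude Artifact excursion in microvolts.
#' @param betweenAmplitudeSdLog Log-normal sd of per-participant amplitude
#'   scaling in [simulateExperiment()].
#' @param betweenLatencySd Gaussian sd (seconds) of per-participant kernel
#'   latency jitter.
#' @param padEnd Seconds of silence appended after the last response tail.
#' @param seed Integer RNG seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(samplingRate = 128,
                             channels = scalpChannels64(),
                             amplitudeWord = 1, amplitudeSyllable = 1,
                             amplitudeAm = 1,
                             kernelWord = makeErpKernel("gamma", 0.18, 0.4,
                               samplingRate = samplingRate),
                             kernelSyllable = makeErpKernel("gamma", 0.09, 0.15,
                               samplingRate = samplingRate),
                             kernelAm = makeErpKernel("gamma", 0.12, 0.12,
                               samplingRate = samplingRate),
                             topographyWord = topographyPreset("centrofrontal",
                               channels),
                             topographySyllable = topographyPreset("centrofrontal",
                               channels),
                             topographyAm = topographyPreset("temporal",
                               channels),
                             noiseSd = 10, noiseExponent = 1, eogSd = 40,
                             eogGainV = defaultEogGain(channels),
                             eogGainH = defaultEogGain(channels, scale = 0.08),
                             artifactRate = 0, artifactAmplitude = 500,
                             betweenAmplitudeSdLog = 0.3,
                             betweenLatencySd = 0.02,
                             padEnd = 1, seed = 1L) {
  new("SimulationConfig", samplingRate = samplingRate, channels = channels,
      kernelWord = kernelWord, kernelSyllable = kernelSyllable,
      kernelAm = kernelAm, amplitudeWord = amplitudeWord,
      amplitudeSyllable = amplitudeSyllable, amplitudeAm = amplitudeAm,
      topographyWord = topographyWord,
      topographySyllable = topographySyllable, topographyAm = topographyAm,
      noiseSd = noiseSd, noiseExponent = noiseExponent, eogSd = eogSd,
      eogGainV = eogGainV, eogGainH = eogGainH, artifactRate = artifactRate,
      artifactAmplitude = artifactAmplitude,
      betweenAmplitudeSdLog = betweenAmplitudeSdLog,
      betweenLatencySd = betweenLatencySd, padEnd = padEnd,
      seed = as.integer(seed))
}

# FFT-shaped 1/f^alpha Gaussian noise, standardised to unit sd.
.oneOverFNoise <- function(n, alpha) {
  m <- stats::nextn(n, c(2, 3, 5))          # composite length for FFT speed
  x <- rnorm(m)
  X <- fft(x)
  f <- c(1, seq_len(m - 1))                 # DC handled separately
  f <- pmin(f, m - f + 1)                   # mirror for negative frequencies
  g <- f^(-alpha / 2)
  g[1] <- 0
  y <- Re(fft(X * g, inverse = TRUE))[seq_len(n)] / m
  s <- sd(y)
  if (s > 0) y / s else y
}

# Convolve an impulse train (event times in seconds) with a kernel; returns a
# series of length n.
.trainResponse <- function(onsets, kernel, fs, n) {
  out <- numeric(n)
  if (!length(onsets)) return(out)
  idx <- timeToSample(onsets, fs) + 1L
  train <- numeric(n)
  keep <- idx >= 1L & idx <= n
  for (i in idx[keep]) train[i] <- train[i] + 1
  k <- kernel@samples
  nf <- n + length(k)
  conv <- Re(fft(fft(c(train, numeric(nf - n))) *
                 fft(c(k, numeric(nf - length(k)))), inverse = TRUE)) / nf
  conv[seq_len(n)]
}

#' Simulate a multichannel EEG recording for one timeline
#'
#' Implements `data = sum_component amplitude * topography (x) (kernel *
#' impulse train) + noise + ocular leakage`, deterministically for a fixed
#' seed. Mastoid channels carry noise only; HEOG/VEOG carry the ocular
#' components plus noise.
#'
#' @param timeline A timed [SyllableTimeline-class].
#' @param config A [SimulationConfig-class].
#' @param seed Optional integer overriding `config@seed`.
#' @return An [EEGRecording-class] with reference state `"raw"`. Ground-truth
#'   metadata (seed, artifact log) is stored in the recording's `meta` list.
#' @export
simulateRecording <- function(timeline, config, seed = NULL) {
  if (timeline@timing == "none") stop("assign timing before simulating")
  if (is.null(seed)) seed <- config@seed
  fs <- config@samplingRate
  ev <- timeline@events
  span <- max(ev$onset + ev$duration) + 0.75 + config@padEnd
  n <- as.integer(ceiling(span * fs))
  scalp <- config@channels
  labels <- c(scalp, .AUX_CHANNELS)
  roles <- c(rep("eeg", length(scalp)), unname(.AUX_ROLES[.AUX_CHANNELS]))
  nCh <- length(labels)

  withSeed(seed, {
    data <- matrix(0, nCh, n, dimnames = list(labels, NULL))
    addComponent <- function(onsets, kernel, amplitude, topo) {
      if (amplitude == 0 || !length(onsets)) return()
      sig <- .trainResponse(onsets, kernel, fs, n)
      data[seq_along(scalp), ] <<- data[seq_along(scalp), , drop = FALSE] +
        amplitude * outer(unname(topo[scalp]), sig)
    }
    addComponent(eventOnsets(timeline, "word"), config@kernelWord,
                 config@amplitudeWord, config@topographyWord)
    addComponent(eventOnsets(timeline, "syllable"), config@kernelSyllable,
                 config@amplitudeSyllable, config@topographySyllable)
    addComponent(eventOnsets(timeline, "amplified"), config@kernelAm,
                 config@amplitudeAm, config@topographyAm)

    if (config@noiseSd > 0)
      for (c in seq_len(nCh))
        data[c, ] <- data[c, ] +
          config@noiseSd * .oneOverFNoise(n, config@noiseExponent)

    if (config@eogSd > 0) {
      ocularV <- cumsum(rnorm(n)); ocularV <- ocularV - mean(ocularV)
      ocularV <- config@eogSd * ocularV / sd(ocularV)
      ocularH <- cumsum(rnorm(n)); ocularH <- ocularH - mean(ocularH)
      ocularH <- config@eogSd * ocularH / sd(ocularH)
      data["VEOG", ] <- data["VEOG", ] + ocularV
      data["HEOG", ] <- data["HEOG", ] + ocularH
      data[seq_along(scalp), ] <- data[seq_along(scalp), , drop = FALSE] +
        outer(unname(config@eogGainV[scalp]), ocularV) +
        outer(unname(config@eogGainH[scalp]), ocularH)
    }

    artifactLog <- data.frame(sample = integer(0), channel = character(0))
    if (config@artifactRate > 0) {
      nArt <- rpois(1, config@artifactRate * n / fs)
      if (nArt > 0) {
        at <- sort(sample.int(n - as.integer(0.2 * fs), nArt))
        for (a in at) {
          chans <- sample(seq_along(scalp), max(1L, length(scalp) %/% 3L))
          dur <- as.integer(0.15 * fs)
          bump <- config@artifactAmplitude *
            sin(pi * seq_len(dur) / dur) * sample(c(-1, 1), 1)
          data[chans, a:(a + dur - 1L)] <-
            data[chans, a:(a + dur - 1L), drop = FALSE] +
            matrix(bump, length(chans), dur, byrow = TRUE)
          artifactLog <- rbind(artifactLog,
            data.frame(sample = a, channel = labels[chans]))
        }
      }
    }

    new("EEGRecording", data = data, samplingRate = fs,
        channelLabels = labels, channelRoles = roles,
        referenceState = "raw", provenance = "simulate",
        meta = list(seed = seed, artifactLog = artifactLog,
                    condition = timeline@condition))
  })
}

#' Simulate a multi-participant experiment
#'
#' Runs [simulateRecording()] for every participant x condition cell with
#' per-participant amplitude scaling (log-normal, sd
#' `betweenAmplitudeSdLog`) and kernel latency jitter (Gaussian, sd
#' `betweenLatencySd`), all seeds derived deterministically from
#' `masterSeed`.
#'
#' @param nParticipants Number of simulated participants (>= 1).
#' @param timelines Named list of timed [SyllableTimeline-class] objects, one
#'   per condition.
#' @param config A [SimulationConfig-class].
#' @param masterSeed Integer master seed.
#' @return A list of length `nParticipants`; each element is a named list of
#'   [EEGRecording-class] objects over conditions.
#' @export
simulateExperiment <- function(nParticipants, timelines, config,
                               masterSeed = 1L) {
  if (nParticipants < 1) stop("nParticipants must be >= 1")
  if (is.null(names(timelines)) || any(!nzchar(names(timelines))))
    stop("'timelines' must be a named list of conditions")
  seeds <- deriveSeeds(masterSeed, nParticipants * (length(timelines) + 1L))
  si <- 0L
  lapply(seq_len(nParticipants), function(p) {
    si <<- si + 1L
    jitter <- withSeed(seeds[si], list(
      amp = exp(rnorm(1, 0, config@betweenAmplitudeSdLog)),
      lat = rnorm(1, 0, config@betweenLatencySd)))
    cfg <- config
    cfg@amplitudeWord <- config@amplitudeWord * jitter$amp
    cfg@amplitudeSyllable <- config@amplitudeSyllable * jitter$amp
    cfg@amplitudeAm <- config@amplitudeAm * jitter$amp
    if (config@betweenLatencySd > 0) {
      cfg@kernelWord <- .shiftKernel(config@kernelWord, jitter$lat)
      cfg@kernelSyllable <- .shiftKernel(config@kernelSyllable, jitter$lat)
      cfg@kernelAm <- .shiftKernel(config@kernelAm, jitter$lat)
    }
    recs <- lapply(seq_along(timelines), function(ci) {
      si <<- si + 1L
      simulateRecording(timelines[[ci]], cfg, seed = seeds[si])
    })
    names(recs) <- names(timelines)
    recs
  })
}
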