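# S4 class definitions for the frequency-tagging pipeline.

#' @import methods
NULL

#' SyllableTimeline: syllable/word event structure of a stimulus
#'
#' Ordered syllable events of a constructed narrative. Each syllable carries
#' its within-sentence parity (sigma1 = odd position, sigma2 = even position),
#' word membership, amplification flag and, once timing has been assigned,
#' onset and duration in seconds. Sentences always contain an even number of
#' syllables; a punctuation gap follows the last syllable of each sentence.
#'
#' @slot events data.frame with one row per syllable and columns
#'   `onset`, `duration` (seconds; `NA` until timing assigned), `parity`
#'   (integer 1 or 2), `wordOnset` (logical), `wordId` (integer),
#'   `wordLength` (integer syllables, 1 or 2), `amplified` (logical),
#'   `sentenceId` (integer), `gapAfter` (logical; punctuation gap follows).
#' @slot mode "metrical" or "nonmetrical".
#' @slot timing "none", "isochronous" or "natural".
#' @slot condition Amplitude condition: "none", "sigma1" or "sigma2".
#' @exportClass SyllableTimeline
setClass("SyllableTimeline",
  representation(events = "data.frame", mode = "character",
                 timing = "character", condition = "character"),
  prototype(mode = "metrical", timing = "none", condition = "none"))

.validTimeline <- function(object) {
  ev <- object@events
  need <- c("onset", "duration", "parity", "wordOnset", "wordId",
            "wordLength", "amplified", "sentenceId", "gapAfter")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (!object@mode %in% c("metrical", "nonmetrical"))
    return("mode must be 'metrical' or 'nonmetrical'")
  if (!object@timing %in% c("none", "isochronous", "natural"))
    return("timing must be 'none', 'isochronous' or 'natural'")
  if (!object@condition %in% c("none", "sigma1", "sigma2"))
    return("condition must be 'none', 'sigma1' or 'sigma2'")
  if (!all(ev$parity %in% 1:2)) return("parity must be 1 or 2")
  sylPerSentence <- table(ev$sentenceId)
  if (any(sylPerSentence %% 2 != 0))
    return("every sentence must contain an even number of syllables")
  if (object@timing != "none") {
    if (anyNA(ev$onset) || anyNA(ev$duration))
      return("onset/duration must be assigned when timing != 'none'")
    if (any(diff(ev$onset) <= 0))
      return("syllable onsets must be strictly increasing")
  }
  if (object@mode == "metrical" && any(ev$parity == 1 & !ev$wordOnset))
    return("metrical mode requires every sigma1 syllable to be a word onset")
  if (object@mode == "nonmetrical") {
    ok <- tapply(ev$parity == 1 & !ev$wordOnset, ev$sentenceId, any)
    if (!all(ok))
      return("nonmetrical mode requires >= 1 sigma1 non-onset per sentence")
  }
  if (object@condition == "sigma1" && !identical(ev$amplified, ev$parity == 1L))
    return("condition 'sigma1' requires amplified flags on exactly the sigma1 syllables")
  if (object@condition == "sigma2" && !identical(ev$amplified, ev$parity == 2L))
    return("condition 'sigma2' requires amplified flags on exactly the sigma2 syllables")
  if (object@condition == "none" && any(ev$amplified))
    return("condition 'none' requires all amplified flags FALSE")
  TRUE
}
setValidity("SyllableTimeline", .validTimeline)

#' StimulusEnvelope: rendered amplitude envelope of a stimulus
#'
#' @slot samples Non-negative amplitude samples (arbitrary units).
#' @slot samplingRate Sampling rate in Hz.
#' @exportClass StimulusEnvelope
setClass("StimulusEnvelope",
  representation(samples = "numeric", samplingRate = "numeric"))
setValidity("StimulusEnvelope", function(object) {
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a positive scalar")
  if (any(object@samples < 0)) return("envelope samples must be >= 0")
  TRUE
})

#' ErpKernel: ground-truth evoked-response kernel for simulation
#'
#' A sampled single-trial evoked response shape, supported on [0, 0.75] s and
#' normalised to unit peak magnitude before amplitude scaling.
#'
#' @slot samples Kernel samples starting at lag 0.
#' @slot samplingRate Hz.
#' @slot shape Construction used ("gamma", "windowed_sine" or "impulse").
#' @slot latency,width,polarity Construction parameters (seconds, seconds, +-1).
#' @exportClass ErpKernel
setClass("ErpKernel",
  representation(samples = "numeric", samplingRate = "numeric",
                 shape = "character", latency = "numeric", width = "numeric",
                 polarity = "numeric"))
setValidity("ErpKernel", function(object) {
  if (!all(is.finite(object@samples))) return("kernel samples must be finite")
  if (length(object@samples) > round(0.75 * object@samplingRate) + 1L)
    return("kernel support must lie within [0, 0.75] s")
  TRUE
})

#' EEGRecording: multichannel EEG/EOG/mastoid time series
#'
#' @slot data Numeric matrix, channels x samples, in microvolts.
#' @slot samplingRate Hz.
#' @slot channelLabels Unique channel names.
#' @slot channelRoles One of "eeg", "eog", "mastoid" per channel.
#' @slot referenceState "raw" or "mastoid_avg".
#' @slot mask Logical matrix of per-sample artifact marks (0 x 0 when unset).
#' @slot provenance Character vector of processing steps applied, in order.
#' @slot meta List of free-form metadata (simulation seed, ground truth, logs).
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", samplingRate = "numeric",
                 channelLabels = "character", channelRoles = "character",
                 referenceState = "character", mask = "matrix",
                 provenance = "character", meta = "list"),
  prototype(referenceState = "raw", mask = matrix(logical(0), 0, 0),
            provenance = character(0), meta = list()))
setValidity("EEGRecording", function(object) {
  if (nrow(object@data) != length(object@channelLabels))
    return("data must have one row per channel label")
  if (anyDuplicated(object@channelLabels)) return("channel labels must be unique")
  if (length(object@channelRoles) != length(object@channelLabels))
    return("channelRoles must match channelLabels in length")
  if (!all(object@channelRoles %in% c("eeg", "eog", "mastoid")))
    return("channelRoles must be 'eeg', 'eog' or 'mastoid'")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a positive scalar")
  if (!object@referenceState %in% c("raw", "mastoid_avg"))
    return("referenceState must be 'raw' or 'mastoid_avg'")
  if (length(object@mask) && !identical(dim(object@mask), dim(object@data)))
    return("mask must be empty or have the same dimensions as data")
  TRUE
})

#' EpochedResponse: trials x channels x samples at fixed epoch length
#'
#' @slot data Numeric array `[trial, channel, sample]` (microvolts).
#' @slot samplingRate Hz.
#' @slot epochDuration Seconds per trial (default pipeline value 7 s).
#' @slot channelLabels Channel names (scalp EEG only after segmentation).
#' @slot keptTrials Indices (into the original trial grid) of retained trials.
#' @slot rejectionLog data.frame of dropped trials and reasons.
#' @slot trialMasked Logical per original trial: contains masked samples.
#' @slot provenance Processing chain inherited from the source recording.
#' @exportClass EpochedResponse
setClass("EpochedResponse",
  representation(data = "array", samplingRate = "numeric",
                 epochDuration = "numeric", channelLabels = "character",
                 keptTrials = "integer", rejectionLog = "data.frame",
                 trialMasked = "logical", provenance = "character"))
setValidity("EpochedResponse", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array [trial, channel, sample]")
  if (d[2] != length(object@channelLabels))
    return("second dimension must match channelLabels")
  if (d[3] != round(object@epochDuration * object@samplingRate))
    return("samples per trial must equal round(epochDuration * samplingRate)")
  if (any(object@keptTrials < 1L))
    return("keptTrials must be positive indices")
  TRUE
})

#' FreqSpectrum: one-sided complex spectrum of a trial-averaged response
#'
#' Coefficients are the DFT of the coherently trial-averaged waveform divided
#' by the sample count, so a unit-amplitude cosine contributes magnitude 1/2
#' at its bin with phase equal to its cosine phase. Bin spacing is
#' 1/epochDuration Hz (1/7 Hz for 7-s trials).
#'
#' @slot coefficients Complex matrix, channels x bins.
#' @slot frequencies Bin frequencies in Hz.
#' @slot epochDuration Seconds.
#' @slot nTrialsAveraged Number of trials in the coherent average.
#' @slot channelLabels Channel names.
#' @exportClass FreqSpectrum
setClass("FreqSpectrum",
  representation(coefficients = "matrix", frequencies = "numeric",
                 epochDuration = "numeric", nTrialsAveraged = "integer",
                 channelLabels = "character"))
setValidity("FreqSpectrum", function(object) {
  if (ncol(object@coefficients) != length(object@frequencies))
    return("one coefficient column per frequency bin")
  if (nrow(object@coefficients) != length(object@channelLabels))
    return("one coefficient row per channel")
  TRUE
})

#' PhaseStat: circular mean direction and resultant length
#'
#' @slot meanAngle Mean direction in degrees, in (-180, 180]; `NA` when the
#'   mean direction is undefined (resultant length below tolerance).
#' @slot resultantLength Mean resultant length in [0, 1].
#' @slot n Number of angles averaged.
#' @slot defined FALSE when the mean direction is degenerate.
#' @exportClass PhaseStat
setClass("PhaseStat",
  representation(meanAngle = "numeric", resultantLength = "numeric",
                 n = "integer", defined = "logical"))
setValidity("PhaseStat", function(object) {
  if (object@resultantLength < -1e-9 || object@resultantLength > 1 + 1e-9)
    return("resultantLength must lie in [0, 1]")
  TRUE
})

#' StatResult: outcome of a bootstrap/permutation test
#'
#' @slot method Name of the test.
#' @slot statistic Observed statistic.
#' @slot pValue p-value in (0, 1]; respects the floor 1/(nResamples + 1).
#' @slot nResamples Resample/permutation count.
#' @slot ci Optional confidence interval (length 0 or 2).
#' @slot ciLevel Nominal CI coverage (fraction).
#' @slot sidedness "one-sided" or "two-sided".
#' @slot fdrAdjustedP Optional FDR-adjusted p (length 0 or 1).
#' @slot seed RNG seed used.
#' @slot extra List of method-specific extras (e.g. resampled distribution).
#' @exportClass StatResult
setClass("StatResult",
  representation(method = "character", statistic = "numeric",
                 pValue = "numeric", nResamples = "integer", ci = "numeric",
                 ciLevel = "numeric", sidedness = "character",
                 fdrAdjustedP = "numeric", seed = "integer", extra = "list"),
  prototype(ci = numeric(0), ciLevel = 0.95, fdrAdjustedP = numeric(0),
            extra = list()))
setValidity("StatResult", function(object) {
  if (length(object@pValue) == 1L &&
      (object@pValue <= 0 || object@pValue > 1))
    return("pValue must lie in (0, 1]")
  if (length(object@fdrAdjustedP) == 1L && length(object@pValue) == 1L &&
      object@fdrAdjustedP < object@pValue - 1e-12)
    return("fdrAdjustedP must be >= pValue")
  TRUE
})

#' ClusterResult: cluster-based permutation test outcome
#'
#' @slot clusters data.frame with columns `start`, `end` (seconds, inclusive
#'   interval of suprathreshold run), `stat` (sum of t-values), `p`.
#' @slot nPermutations Permutation count.
#' @slot clusterAlpha Pointwise two-sided alpha forming clusters.
#' @slot tThreshold |t| threshold corresponding to clusterAlpha.
#' @slot nullMax Permutation distribution of the max |cluster stat|.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(clusters = "data.frame", nPermutations = "integer",
                 clusterAlpha = "numeric", tThreshold = "numeric",
                 nullMax = "numeric"))
setValidity("ClusterResult", function(object) {
  cl <- object@clusters
  if (nrow(cl) > 1) {
    o <- order(cl$start)
    if (any(cl$start[o][-1] <= cl$end[o][-nrow(cl)]))
      return("clusters must be non-overlapping")
  }
  TRUE
})

#' SyllableResponseSet: per-syllable 0-750 ms response segments
#'
#' @slot segments Array `[syllable, channel, sample]`, segment length
#'   `round(0.75 * samplingRate)`.
#' @slot kept Logical per syllable; FALSE when the segment ran past the end of
#'   the recording and was zero-filled (grid slot preserved).
#' @slot samplingRate Hz.
#' @slot channelLabels Channel names.
#' @slot timeline The source SyllableTimeline (word bookkeeping travels with j).
#' @exportClass SyllableResponseSet
setClass("SyllableResponseSet",
  representation(segments = "array", kept = "logical",
                 samplingRate = "numeric", channelLabels = "character",
                 timeline = "SyllableTimeline"))
setValidity("SyllableResponseSet", function(object) {
  d <- dim(object@segments)
  if (length(d) != 3L) return("segments must be [syllable, channel, sample]")
  if (d[3] != round(0.75 * object@samplingRate))
    return("segment length must be round(0.75 * samplingRate)")
  if (d[1] != length(object@kept)) return("one kept flag per syllable")
  TRUE
})

#' ERPPair: baseline-corrected sigma1/sigma2 ERPs for disyllabic words
#'
#' @slot erpS1,erpS2 Channels x samples ERP matrices over [-0.1, 0.75] s
#'   relative to syllable onset, baseline-corrected on [-0.1, 0) s.
#' @slot time Sample times in seconds relative to syllable onset.
#' @slot samplingRate Hz.
#' @slot channelLabels Channel names.
#' @slot nWords Number of disyllabic words averaged.
#' @exportClass ERPPair
setClass("ERPPair",
  representation(erpS1 = "matrix", erpS2 = "matrix", time = "numeric",
                 samplingRate = "numeric", channelLabels = "character",
                 nWords = "integer"))
setValidity("ERPPair", function(object) {
  if (!identical(dim(object@erpS1), dim(object@erpS2)))
    return("erpS1 and erpS2 must have identical shapes")
  if (ncol(object@erpS1) != length(object@time))
    return("time must match the sample dimension")
  TRUE
})

#' WarpedResponse: response warped onto the 4-Hz isochronous grid
#'
#' @slot recording The warped multichannel series as an EEGRecording.
#' @slot timeline The same syllable sequence with isochronous timing, for
#'   downstream sentence-aware segmentation.
#' @exportClass WarpedResponse
setClass("WarpedResponse",
  representation(recording = "EEGRecording", timeline = "SyllableTimeline"))

#' FilterSpec: linear-phase FIR band-pass specification
#'
#' @slot taps Symmetric coefficient vector (N + 1 taps; group delay N/2).
#' @slot N Filter order (tap count minus 1); the group delay in samples is N/2.
#' @slot band Pass band `[low, high]` in Hz.
#' @slot windowDuration Design window length in seconds.
#' @slot samplingRate Hz.
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(taps = "numeric", N = "integer", band = "numeric",
                 windowDuration = "numeric", samplingRate = "numeric"))
setValidity("FilterSpec", function(object) {
  if (length(object@taps) != object@N + 1L)
    return("tap count must equal N + 1")
  if (max(abs(object@taps - rev(object@taps))) > 1e-12)
    return("taps must be symmetric (linear phase)")
  if (object@N %% 2L != 0L)
    return("N must be even so that the N/2 delay is an integer")
  TRUE
})

#' SimulationConfig: ground truth for the forward EEG simulator
#'
#' Houses the evoked-response kernels, amplitudes and topographies of the
#' word-locked, syllable-locked and AM-locked components, the background-noise
#' model, ocular artifact generation, and between-subject variability.
#'
#' @slot samplingRate Hz (2048 for the full recording chain; 128 fast mode).
#' @slot channels Scalp channel labels simulated (HEOG/VEOG/M1/M2 are added).
#' @slot kernelWord,kernelSyllable,kernelAm ErpKernel ground truths.
#' @slot amplitudeWord,amplitudeSyllable,amplitudeAm Scale factors (microvolts).
#' @slot topographyWord,topographySyllable,topographyAm Named weight maps.
#' @slot noiseSd Background-noise standard deviation per channel (microvolts).
#' @slot noiseExponent Spectral slope alpha of the 1/f^alpha background.
#' @slot eogSd Ocular component standard deviation in the EOG channels.
#' @slot eogGainV,eogGainH Per-scalp-channel leakage of the vertical /
#'   horizontal ocular components.
#' @slot artifactRate Large-artifact event rate (events per second).
#' @slot artifactAmplitude Artifact excursion amplitude (microvolts).
#' @slot betweenAmplitudeSdLog Between-subject log-normal amplitude sd.
#' @slot betweenLatencySd Between-subject Gaussian latency jitter sd (s).
#' @slot padEnd Zero padding after the last syllable response (seconds).
#' @slot seed RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(samplingRate = "numeric", channels = "character",
                 kernelWord = "ErpKernel", kernelSyllable = "ErpKernel",
                 kernelAm = "ErpKernel", amplitudeWord = "numeric",
                 amplitudeSyllable = "numeric", amplitudeAm = "numeric",
                 topographyWord = "numeric", topographySyllable = "numeric",
                 topographyAm = "numeric", noiseSd = "numeric",
                 noiseExponent = "numeric", eogSd = "numeric",
                 eogGainV = "numeric", eogGainH = "numeric",
                 artifactRate = "numeric", artifactAmplitude = "numeric",
                 betweenAmplitudeSdLog = "numeric", betweenLatencySd = "numeric",
                 padEnd = "numeric", seed = "integer"))
setValidity("SimulationConfig", function(object) {
  for (nm in c("topographyWord", "topographySyllable", "topographyAm")) {
    topo <- slot(object, nm)
    if (!all(object@channels %in% names(topo)))
      return(sprintf("%s must name every simulated channel", nm))
    if (abs(max(abs(topo)) - 1) > 1e-9)
      return(sprintf("%s must have max |weight| = 1", nm))
  }
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})
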