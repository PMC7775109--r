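# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for rhythmtag containers
#' @param object A rhythmtag S4 object.
#' @description Slot access goes through these accessors; slots are internal.
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setGeneric("syllableEvents", function(object) standardGeneric("syllableEvents"))
#' @rdname accessors
#' @export
setGeneric("nSyllables", function(object) standardGeneric("nSyllables"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("keptTrials", function(object) standardGeneric("keptTrials"))
#' @rdname accessors
#' @export
setGeneric("rejectionLog", function(object) standardGeneric("rejectionLog"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("spectralCoefficients", function(object) standardGeneric("spectralCoefficients"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(object) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("referenceState", function(object) standardGeneric("referenceState"))
#' @rdname accessors
#' @export
setGeneric("artifactMask", function(object) standardGeneric("artifactMask"))
#' @rdname accessors
#' @export
setGeneric("meanAngle", function(object) standardGeneric("meanAngle"))
#' @rdname accessors
#' @export
setGeneric("resultantLength", function(object) standardGeneric("resultantLength"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochedResponse", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "ErpKernel", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "StimulusEnvelope", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochedResponse", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "FreqSpectrum", function(object) object@channelLabels)
#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("eegData", "EpochedResponse", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("syllableEvents", "SyllableTimeline", function(object) object@events)
#' @rdname accessors
#' @export
setMethod("nSyllables", "SyllableTimeline", function(object) nrow(object@events))
#' @rdname accessors
#' @export
setMethod("nTrials", "EpochedResponse", function(object) dim(object@data)[1])
#' @rdname accessors
#' @export
setMethod("keptTrials", "EpochedResponse", function(object) object@keptTrials)
#' @rdname accessors
#' @export
setMethod("rejectionLog", "EpochedResponse", function(object) object@rejectionLog)
#' @rdname accessors
#' @export
setMethod("frequencies", "FreqSpectrum", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("spectralCoefficients", "FreqSpectrum", function(object) object@coefficients)
#' @rdname accessors
#' @export
setMethod("pValue", "StatResult", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("statistic", "StatResult", function(object) object@statistic)
#' @rdname accessors
#' @export
setMethod("confInt", "StatResult", function(object) object@ci)
#' @rdname accessors
#' @export
setMethod("provenance", "EEGRecording", function(object) object@provenance)
#' @rdname accessors
#' @export
setMethod("provenance", "EpochedResponse", function(object) object@provenance)
#' @rdname accessors
#' @export
setMethod("referenceState", "EEGRecording", function(object) object@referenceState)
#' @rdname accessors
#' @export
setMethod("artifactMask", "EEGRecording", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("meanAngle", "PhaseStat", function(object) object@meanAngle)
#' @rdname accessors
#' @export
setMethod("resultantLength", "PhaseStat", function(object) object@resultantLength)
#' @rdname accessors
#' @export
setMethod("clusters", "ClusterResult", function(object) object@clusters)

setMethod("show", "SyllableTimeline", function(object) {
  ev <- object@events
  cat(sprintf("SyllableTimeline: %d syllables, %d sentences, %d words\n",
              nrow(ev), length(unique(ev$sentenceId)),
              length(unique(ev$wordId))))
  cat(sprintf("  mode: %s | timing: %s | condition: %s\n",
              object@mode, object@timing, object@condition))
  if (!anyNA(ev$onset))
    cat(sprintf("  span: %.3f s\n", max(ev$onset + ev$duration)))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  cat(sprintf("  reference: %s | masked samples: %d\n", object@referenceState,
              if (length(object@mask)) sum(object@mask) else 0L))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "EpochedResponse", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochedResponse: %d trials x %d channels x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], object@epochDuration, object@samplingRate))
  cat(sprintf("  kept trials: %d | rejected: %d\n", d[1],
              nrow(object@rejectionLog)))
})

setMethod("show", "FreqSpectrum", function(object) {
  cat(sprintf("FreqSpectrum: %d channels x %d bins, resolution %.4f Hz, %d trials averaged\n",
              nrow(object@coefficients), ncol(object@coefficients),
              1 / object@epochDuration, object@nTrialsAveraged))
})

setMethod("show", "PhaseStat", function(object) {
  if (object@defined)
    cat(sprintf("PhaseStat: mean %.2f deg, resultant length %.3f (n = %d)\n",
                object@meanAngle, object@resultantLength, object@n))
  else
    cat(sprintf("PhaseStat: mean direction undefined (resultant length %.2e, n = %d)\n",
                object@resultantLength, object@n))
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult [%s, %s]: statistic = %.4g, p = %.4g (%d resamples)\n",
              object@method, object@sidedness, object@statistic, object@pValue,
              object@nResamples))
  if (length(object@ci) == 2L)
    cat(sprintf("  %g%% CI: [%.4g, %.4g]\n", 100 * object@ciLevel,
                object@ci[1], object@ci[2]))
  if (length(object@fdrAdjustedP))
    cat(sprintf("  FDR-adjusted p: %.4g\n", object@fdrAdjustedP))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cluster(s), %d permutations, |t| > %.3f\n",
              nrow(object@clusters), object@nPermutations, object@tThreshold))
  if (nrow(object@clusters)) print(object@clusters)
})

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf("FilterSpec: %d taps (N = %d, delay %d samples), band [%g, %g] Hz @ %g Hz\n",
              length(object@taps), object@N, object@N %/% 2L,
              object@band[1], object@band[2], object@samplingRate))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %g Hz, %d scalp channels\n",
              object@samplingRate, length(object@channels)))
  cat(sprintf("  amplitudes (uV): word %.2f, syllable %.2f, AM %.2f\n",
              object@amplitudeWord, object@amplitudeSyllable, object@amplitudeAm))
  cat(sprintf("  noise sd %.2f uV (1/f^%.2f), EOG sd %.1f, artifact rate %.3f/s\n",
              object@noiseSd, object@noiseExponent, object@eogSd,
              object@artifactRate))
})
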