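# Shared fixture builders: everything is generated in code at test time.

fewChannels <- c("FCz", "Fz", "Cz", "T7")

makeRecording <- function(data, fs = 128,
                          labels = paste0("ch", seq_len(nrow(data))),
                          roles = rep("eeg", nrow(data)),
                          reference = "raw") {
  new("EEGRecording", data = data, samplingRate = fs, channelLabels = labels,
      channelRoles = roles, referenceState = reference)
}

makeEpochs <- function(dat, fs = 128, epochDuration = 7,
                       labels = paste0("ch", seq_len(dim(dat)[2]))) {
  new("EpochedResponse", data = dat, samplingRate = fs,
      epochDuration = epochDuration, channelLabels = labels,
      keptTrials = seq_len(dim(dat)[1]),
      rejectionLog = data.frame(trial = integer(0), reason = character(0)),
      trialMasked = rep(FALSE, dim(dat)[1]), provenance = "fixture")
}

# Noise-free simulation config with a single active component. The AM kernel
# support is kept within 0.25 s so the AM-locked response is exactly periodic
# at the word rate within sentences (see the methods vignette).
componentConfig <- function(component = c("word", "syllable", "am", "none"),
                            channels = fewChannels, fs = 128, seed = 1L) {
  component <- match.arg(component)
  simulationConfig(
    samplingRate = fs, channels = channels,
    amplitudeWord = as.numeric(component == "word"),
    amplitudeSyllable = as.numeric(component == "syllable"),
    amplitudeAm = as.numeric(component == "am"),
    kernelAm = makeErpKernel("gamma", 0.08, 0.12, samplingRate = fs),
    noiseSd = 0, eogSd = 0, artifactRate = 0, seed = seed)
}

# sigma1/sigma2 amplitude-condition pair over the same metrical text.
conditionPair <- function(nSyllables = 240, seed = 3L) {
  iso <- assignIsochronousTiming(generateMetricalTimeline(nSyllables,
                                                          seed = seed))
  list(s1 = applyAmplitudeCondition(iso, "sigma1"),
       s2 = applyAmplitudeCondition(iso, "sigma2"))
}

# Noise-free pipeline without the band-pass stage (nothing to filter out and
# the 6-s filter's sentence-boundary transients would blur exact phase
# identities).
cleanEpochs <- function(recording, timeline) {
  suppressWarnings(preprocessRecording(recording, timeline, doFilter = FALSE,
                                       doEogRegression = FALSE,
                                       doMask = FALSE, doReject = FALSE))
}
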