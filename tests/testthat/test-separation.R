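# Word/AM component separation by condition averaging, topography
# normalisation, disyllabic-word ERPs.

# 2-Hz power of the first channel of a channels x samples waveform (7-s
# trial grid assumed).
pow2Hz <- function(w, fs = 128) {
  sp <- waveformSpectrum(w, fs)
  spectrumPower(sp)[1, which.min(abs(frequencies(sp) - 2))]
}

# Noise-free condition epochs for a given component, as trial-averaged
# channels x samples waveforms.
conditionWaveforms <- function(component, nSyllables = 240, seed = 3L) {
  pair <- conditionPair(nSyllables, seed)
  cfg <- componentConfig(component)
  list(w1 = rhythmtag:::.asWaveform(cleanEpochs(simulateRecording(pair$s1, cfg),
                                                pair$s1)),
       w2 = rhythmtag:::.asWaveform(cleanEpochs(simulateRecording(pair$s2, cfg),
                                                pair$s2)),
       pair = pair, cfg = cfg)
}

test_that("word averaging annihilates the AM-locked 2-Hz component", {
  am <- conditionWaveforms("am")
  expect_gt(pow2Hz(am$w1), 1e-6)                    # component present
  w <- wordAverage(am$w1, am$w2)
  expect_lt(pow2Hz(w), 1e-20 * pow2Hz(am$w1))       # cancelled to precision
  expect_identical(attr(w, "component"), "word_response")
  # identical inputs pass through unchanged
  expect_equal(unname(wordAverage(am$w1, am$w1)), unname(am$w1),
               ignore_attr = TRUE)
  expect_error(wordAverage(am$w1, am$w2[, -1]), "shape")
})

test_that("AM averaging annihilates the word-locked 2-Hz component", {
  wd <- conditionWaveforms("word")
  expect_gt(pow2Hz(wd$w1), 1e-6)
  a <- amAverage(wd$w1, wd$w2, samplingRate = 128)
  expect_lt(pow2Hz(a), 1e-20 * pow2Hz(wd$w1))
  expect_identical(attr(a, "component"), "am_response")
  # delay 0 degenerates to the word average
  expect_equal(unname(amAverage(wd$w1, wd$w2, delay = 0, samplingRate = 128)),
               unname(wordAverage(wd$w1, wd$w2)), ignore_attr = TRUE)
  expect_error(amAverage(wd$w1, wd$w2, delay = 0.1001, samplingRate = 128),
               "integer number of samples")
})

test_that("separation recovers each injected component amplitude within 1%", {
  pair <- conditionPair(240)
  mixed <- simulationConfig(samplingRate = 128, channels = fewChannels,
                            amplitudeWord = 1.3, amplitudeSyllable = 0.8,
                            amplitudeAm = 0.6,
                            kernelAm = makeErpKernel("gamma", 0.08, 0.12,
                                                     samplingRate = 128),
                            noiseSd = 0, eogSd = 0)
  wordOnly <- mixed; wordOnly@amplitudeSyllable <- 0; wordOnly@amplitudeAm <- 0
  amOnly <- mixed; amOnly@amplitudeWord <- 0; amOnly@amplitudeSyllable <- 0
  w1 <- rhythmtag:::.asWaveform(cleanEpochs(simulateRecording(pair$s1, mixed),
                                            pair$s1))
  w2 <- rhythmtag:::.asWaveform(cleanEpochs(simulateRecording(pair$s2, mixed),
                                            pair$s2))
  truthWord <- pow2Hz(rhythmtag:::.asWaveform(
    cleanEpochs(simulateRecording(pair$s1, wordOnly), pair$s1)))
  truthAm <- pow2Hz(rhythmtag:::.asWaveform(
    cleanEpochs(simulateRecording(pair$s1, amOnly), pair$s1)))
  recWord <- pow2Hz(wordAverage(w1, w2))
  recAm <- pow2Hz(amAverage(w1, w2, samplingRate = 128))
  expect_lt(abs(sqrt(recWord) - sqrt(truthWord)) / sqrt(truthWord), 0.01)
  expect_lt(abs(sqrt(recAm) - sqrt(truthAm)) / sqrt(truthAm), 0.01)
})

test_that("the 2-Hz decomposition reconstructs each condition exactly", {
  # orthogonality of the separation at 2 Hz in the noise-free two-component
  # model: word + (AM shifted back into condition alignment) rebuilds each
  # input's 2-Hz coefficient
  pair <- conditionPair(240)
  mixed <- simulationConfig(samplingRate = 128, channels = fewChannels,
                            amplitudeWord = 1, amplitudeSyllable = 0,
                            amplitudeAm = 0.7,
                            kernelAm = makeErpKernel("gamma", 0.08, 0.12,
                                                     samplingRate = 128),
                            noiseSd = 0, eogSd = 0)
  w1 <- rhythmtag:::.asWaveform(cleanEpochs(simulateRecording(pair$s1, mixed),
                                            pair$s1))
  w2 <- rhythmtag:::.asWaveform(cleanEpochs(simulateRecording(pair$s2, mixed),
                                            pair$s2))
  word <- wordAverage(w1, w2)
  am <- amAverage(w1, w2, samplingRate = 128)
  coef2 <- function(w) {
    sp <- waveformSpectrum(w, 128)
    spectralCoefficients(sp)[, which.min(abs(frequencies(sp) - 2))]
  }
  # in sigma2-condition alignment the AM response is as measured; rotating
  # the AM average back by -0.25 s (circularly, within the phase-continuous
  # trial) realigns it with the sigma1 condition
  amS1 <- am[, c(33:896, 1:32), drop = FALSE]
  expect_equal(coef2(word) + coef2(amS1), coef2(w1), tolerance = 1e-9)
  expect_equal(coef2(word) + coef2(am), coef2(w2), tolerance = 1e-9)
})

test_that("averaging independent noise halves the expected power", {
  set.seed(21)
  p1 <- p2 <- numeric(40)
  for (r in seq_len(40)) {
    a <- matrix(rnorm(2 * 896), 2)
    b <- matrix(rnorm(2 * 896), 2)
    p1[r] <- pow2Hz(a)
    p2[r] <- pow2Hz(wordAverage(a, b))
  }
  ratio <- mean(p2) / mean(p1)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.7)
})

test_that("topography normalisation is scale-invariant with unit maximum", {
  m <- c(Fz = 2, Cz = 7, Pz = 1)
  nm <- normalizeTopography(m)
  expect_equal(max(nm), 1)
  expect_equal(nm, normalizeTopography(7 * m))
  expect_equal(unname(normalizeTopography(c(3, 3, 3))), c(1, 1, 1))
  expect_error(normalizeTopography(c(0, 0)), "positive")
  expect_error(normalizeTopography(c(-2, -1)), "positive")
})

test_that("disyllabic ERPs are baseline-corrected word averages", {
  # all-disyllabic text so sigma1 = word onsets and sigma2 = second
  # syllables exactly; kernels confined to one 0.25-s cycle so the ERP
  # difference over the first cycle is the plain kernel difference
  tl <- assignIsochronousTiming(generateMetricalTimeline(240, pDisyllabic = 1,
                                                         seed = 12))
  kS1 <- makeErpKernel("gamma", 0.08, 0.15, samplingRate = 128)
  kS2 <- makeErpKernel("windowed_sine", 0.02, 0.2, samplingRate = 128)
  # sigma1/sigma2 syllables of disyllabic words carry distinct kernels:
  # simulate via word component (sigma1 positions) + custom second-syllable
  # component built as an AM-like train on sigma2 positions
  cfg <- componentConfig("word", channels = c("FCz", "Cz"))
  cfg@kernelWord <- kS1
  s2tl <- applyAmplitudeCondition(tl, "sigma2")   # amplified = sigma2 slots
  cfgB <- componentConfig("am", channels = c("FCz", "Cz"))
  cfgB@kernelAm <- kS2
  dat <- eegData(simulateRecording(tl, cfg)) +
    eegData(simulateRecording(s2tl, cfgB))[, seq_len(ncol(eegData(simulateRecording(tl, cfg))))]
  rec <- makeRecording(dat[1:2, , drop = FALSE], 128,
                       labels = c("FCz", "Cz"), reference = "mastoid_avg")
  erp <- disyllabicERPs(rec, tl)
  expect_gt(erp@nWords, 10)
  base <- erp@time < 0
  # baseline window means are (numerically) zero after correction
  expect_lt(max(abs(rowMeans(erp@erpS1[, base]))), 1e-9)
  expect_lt(max(abs(rowMeans(erp@erpS2[, base]))), 1e-9)
  # the ERP difference waveform recovers the injected kernel difference
  cyc <- 1:30                                  # first 0.25-s cycle
  kDiff <- (kS1@samples - kS2@samples)[cyc]
  post <- erp@time >= 0
  d <- (erp@erpS1 - erp@erpS2)[1, post][cyc]
  expect_gt(cor(d, kDiff * cfg@topographyWord[["FCz"]]), 0.95)
  # a constant recording yields identically zero ERPs
  const <- makeRecording(matrix(5, 2, ncol(dat)), 128,
                         labels = c("FCz", "Cz"), reference = "mastoid_avg")
  erp0 <- disyllabicERPs(const, tl)
  expect_lt(max(abs(erp0@erpS1)), 1e-12)
  # a timeline without disyllabic words is an error
  mono <- assignIsochronousTiming(generateMetricalTimeline(40,
    pDisyllabic = 0, seed = 1))
  expect_error(disyllabicERPs(rec, mono), "disyllabic")
})
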