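# Preprocessing chain: FIR design/application, downsampling, re-referencing,
# EOG regression, masking, segmentation, trial rejection, pipeline order.

test_that("the band-pass FIR meets its design contract", {
  spec <- designBandpassFIR(128)
  expect_equal(length(spec@taps), 6 * 128 + 1)       # 6-s window, odd taps
  expect_equal(spec@taps, rev(spec@taps))            # linear phase
  # -6 dB (|H| = 0.5) at both cut-offs within 5%
  expect_lt(abs(Mod(filterResponse(spec, 0.8)) - 0.5), 0.025)
  expect_lt(abs(Mod(filterResponse(spec, 30)) - 0.5), 0.025)
  expect_lt(Mod(filterResponse(spec, 0)), 0.01)      # DC rejected
  expect_gt(Mod(filterResponse(spec, 4)), 0.98)      # passband
  expect_error(designBandpassFIR(128, low = 0.8, windowDuration = 1),
               "window too short")
  expect_error(designBandpassFIR(128, low = 40, high = 30))
})

test_that("delay compensation leaves in-band signals aligned", {
  fs <- 128
  spec <- designBandpassFIR(fs)
  n <- 30 * fs
  # unit impulse stays at its sample
  x <- matrix(0, 1, n); x[1, 1500] <- 1
  rec <- makeRecording(x, fs)
  y <- eegData(applyFilterCompensated(rec, spec))
  expect_equal(which.max(y[1, ]), 1500)
  # in-band 4-Hz sinusoid: amplitude within 2%, phase within 1 degree
  # (least-squares sinusoid fit oracle)
  t <- (0:(n - 1)) / fs
  rec4 <- makeRecording(rbind(sin(2 * pi * 4 * t)), fs)
  y4 <- eegData(applyFilterCompensated(rec4, spec))[1, ]
  keep <- seq(4 * fs, length(y4) - 4 * fs)     # steady state
  X <- cbind(sin(2 * pi * 4 * t[keep]), cos(2 * pi * 4 * t[keep]))
  beta <- qr.solve(X, y4[keep])
  expect_lt(abs(sqrt(sum(beta^2)) - 1), 0.02)
  expect_lt(abs(atan2(beta[2], beta[1])) * 180 / pi, 1)
  # all-zero input stays zero
  z <- applyFilterCompensated(makeRecording(matrix(0, 2, n), fs), spec)
  expect_true(all(eegData(z) == 0))
  expect_error(applyFilterCompensated(makeRecording(matrix(0, 1, 100), fs),
                                      spec), "shorter")
})

test_that("downsampling preserves in-band content and event timing", {
  fs <- 2048; target <- 128
  n <- 20 * fs
  t <- (0:(n - 1)) / fs
  x <- rbind(cos(2 * pi * 2 * t))
  rec <- makeRecording(x, fs)
  down <- downsampleRecording(rec, target)
  expect_equal(samplingRate(down), target)
  expect_equal(ncol(eegData(down)), n / 16)
  td <- (0:(ncol(eegData(down)) - 1)) / target
  keep <- seq(2 * target, ncol(eegData(down)) - 2 * target)
  X <- cbind(cos(2 * pi * 2 * td[keep]), sin(2 * pi * 2 * td[keep]))
  beta <- qr.solve(X, eegData(down)[1, keep])
  expect_lt(abs(sqrt(sum(beta^2)) - 1), 0.01)       # amplitude within 1%
  # identity when the rate already matches
  same <- downsampleRecording(down, target)
  expect_equal(eegData(same), eegData(down))
  expect_error(downsampleRecording(down, 48), "multiple")
  expect_error(downsampleRecording(down, 4096), "exceeds")
})

test_that("mastoid re-referencing subtracts the mastoid mean from EEG only", {
  set.seed(1)
  dat <- matrix(rnorm(7 * 100), 7, 100)
  labels <- c("Cz", "Fz", "Pz", "HEOG", "VEOG", "M1", "M2")
  roles <- c("eeg", "eeg", "eeg", "eog", "eog", "mastoid", "mastoid")
  rec <- makeRecording(dat, labels = labels, roles = roles)
  ref <- rereferenceMastoids(rec)
  m <- (dat[6, ] + dat[7, ]) / 2
  for (i in 1:3) expect_equal(eegData(ref)[i, ], dat[i, ] - m)
  expect_equal(eegData(ref)[4, ], dat[4, ])         # EOG untouched
  expect_identical(referenceState(ref), "mastoid_avg")
  # common-mode rejection: adding a constant to every channel changes nothing
  rec2 <- makeRecording(dat + 42, labels = labels, roles = roles)
  expect_equal(eegData(rereferenceMastoids(rec2))[1:3, ],
               eegData(ref)[1:3, ])
  # zero mastoids leave the data unchanged
  dat0 <- dat; dat0[6:7, ] <- 0
  rec0 <- makeRecording(dat0, labels = labels, roles = roles)
  expect_equal(eegData(rereferenceMastoids(rec0))[1:3, ], dat0[1:3, ])
  expect_error(rereferenceMastoids(ref), "already")
  expect_error(rereferenceMastoids(makeRecording(dat[1:3, , drop = FALSE],
    labels = labels[1:3], roles = roles[1:3])), "M1/M2")
})

test_that("EOG regression removes ocular leakage and recovers its gain", {
  set.seed(2)
  n <- 5000
  v <- cumsum(rnorm(n)); v <- 50 * (v - mean(v)) / sd(v)
  h <- cumsum(rnorm(n)); h <- 30 * (h - mean(h)) / sd(h)
  brain <- rnorm(n)
  gain <- 0.35
  labels <- c("Fp1", "Cz", "HEOG", "VEOG")
  roles <- c("eeg", "eeg", "eog", "eog")
  dat <- rbind(gain * v + brain, brain, h, v)
  rec <- makeRecording(dat, labels = labels, roles = roles)
  out <- regressOutEOG(rec)
  # residuals orthogonal to both EOG channels
  res <- eegData(out)
  expect_lt(abs(sum(res[1, ] * v)) / sqrt(sum(res[1, ]^2) * sum(v^2)), 1e-8)
  expect_lt(abs(sum(res[1, ] * h)) / sqrt(sum(res[1, ]^2) * sum(h^2)), 1e-8)
  # recovered leakage within 1% of the injected gain
  expect_lt(abs(out@meta$eogBeta["Fp1", "VEOG"] - gain), 0.01 * gain)
  # EEG exactly proportional to VEOG -> residual ~ 0
  pure <- makeRecording(rbind(0.5 * v, brain, h, v), labels = labels,
                        roles = roles)
  expect_lt(max(abs(eegData(regressOutEOG(pure))[1, ])), 1e-8)
  # orthogonal EEG unchanged (up to the fitted coefficient ~ 0)
  expect_equal(eegData(out)[2, ], eegData(regressOutEOG(rec))[2, ])
  # constant EOG skipped with a warning
  const <- makeRecording(rbind(brain, brain, 0 * h, 0 * v), labels = labels,
                         roles = roles)
  expect_warning(regressOutEOG(const), "constant")
})

test_that("artifact masking marks exactly the offending samples", {
  dat <- matrix(0, 2, 1000)
  rec <- makeRecording(dat)
  expect_equal(sum(artifactMask(maskLargeArtifacts(rec))), 0)
  spikes <- cbind(c(1, 300), c(2, 777))       # channel, sample pairs
  dat[1, 300] <- 2000; dat[2, 777] <- -1500
  rec2 <- maskLargeArtifacts(makeRecording(dat))
  expect_equal(which(artifactMask(rec2)[1, ]), 300)
  expect_equal(which(artifactMask(rec2)[2, ]), 777)
  expect_equal(sum(artifactMask(rec2)), 2)
  # values are never altered by masking
  expect_equal(eegData(rec2), dat)
  expect_error(maskLargeArtifacts(rec, threshold = -1), "positive")
})

test_that("segmentation excises onset responses and cuts 7-s trials", {
  tl <- assignIsochronousTiming(generateMetricalTimeline(240, seed = 4))
  cfg <- componentConfig("word")
  rec <- simulateRecording(tl, cfg)
  ep <- cleanEpochs(rec, tl)
  expect_equal(dim(eegData(ep))[3], 896)            # 7 s x 128 Hz
  expect_equal(channelLabels(ep), fewChannels)      # scalp channels only
  # excised prefix per sentence is exactly 0.5 s (two syllables)
  ev <- syllableEvents(tl)
  first <- ev[ev$sentenceId == 1, ]
  expect_equal(first$onset[3] - first$onset[1], 0.5)
  # total kept duration matches the sentence-wise analysis windows
  spans <- tapply(seq_len(nrow(ev)), ev$sentenceId, function(i)
    max(ev$onset[i] + ev$duration[i]) - ev$onset[i][3])
  expect_equal(dim(eegData(ep))[1], floor(sum(spans) / 7))
  expect_error(segmentTrials(makeRecording(matrix(0, 1, 100),
    reference = "mastoid_avg"), tl), "shorter than one trial")
})

test_that("trial rejection drops flagged trials and keeps values intact", {
  set.seed(3)
  dat <- array(rnorm(10 * 2 * 896, sd = 5), dim = c(10, 2, 896))
  ep <- makeEpochs(dat)
  clean <- rejectTrials(ep)
  expect_equal(nTrials(clean), 10)                  # clean data: 0% rejected
  # one 500-uV excursion with a 200-uV threshold drops exactly that trial
  dat2 <- dat; dat2[4, 1, 100:140] <- dat2[4, 1, 100:140] + 500
  rej <- rejectTrials(makeEpochs(dat2))
  expect_identical(rejectionLog(rej)$trial, 4L)
  expect_identical(rejectionLog(rej)$reason, "peak_to_peak")
  expect_equal(eegData(rej), dat2[-4, , , drop = FALSE]) # retained untouched
  # masked samples force rejection
  epM <- makeEpochs(dat)
  epM@trialMasked[7] <- TRUE
  expect_identical(rejectionLog(rejectTrials(epM))$reason, "masked_samples")
  allBad <- makeEpochs(dat)
  allBad@trialMasked[] <- TRUE
  expect_error(rejectTrials(allBad), "all trials rejected")
})

test_that("simulated artifact rates produce plausible rejection fractions", {
  # large-artifact rate chosen so roughly one trial in ten is contaminated;
  # across seeds the rejected fraction stays within the 5-20% band typical
  # of visual inspection
  tl <- assignIsochronousTiming(generateMetricalTimeline(360, seed = 6))
  fracs <- vapply(1:6, function(s) {
    cfg <- simulationConfig(samplingRate = 128, channels = c("FCz", "Cz"),
                            amplitudeWord = 1, amplitudeSyllable = 1,
                            amplitudeAm = 0, noiseSd = 8,
                            artifactRate = 0.015, seed = s)
    rec <- simulateRecording(tl, cfg)
    ep <- suppressWarnings(preprocessRecording(rec, tl, doFilter = FALSE,
                                               doEogRegression = FALSE))
    nrow(rejectionLog(ep)) / (nTrials(ep) + nrow(rejectionLog(ep)))
  }, numeric(1))
  expect_gte(mean(fracs), 0.05)
  expect_lte(mean(fracs), 0.20)
})

test_that("the preprocessing provenance records the documented stage order", {
  tl <- assignIsochronousTiming(generateMetricalTimeline(120, seed = 2))
  cfg <- simulationConfig(samplingRate = 128, channels = c("FCz", "Cz"),
                          noiseSd = 5, seed = 4)
  rec <- simulateRecording(tl, cfg)
  ep <- preprocessRecording(rec, tl)
  expect_identical(provenance(ep),
    c("simulate", "downsample", "rereference", "bandpass", "eog_regression",
      "mask_artifacts", "segment", "reject_trials"))
})

test_that("filtering then segmenting preserves tagged amplitudes within 2%", {
  # every word disyllabic: the tagged components are then exactly periodic,
  # so the trial average is invariant to how many trials each path keeps and
  # the comparison isolates the filter's passband gain. Zero-mean (biphasic)
  # kernels keep the check free of the sentence-length DC pedestal that the
  # 0.8-Hz high-pass removes by design (see the methods vignette).
  tl <- assignIsochronousTiming(generateMetricalTimeline(240, pDisyllabic = 1,
                                                         seed = 9))
  cfg <- simulationConfig(samplingRate = 128, channels = c("FCz", "Cz"),
                          amplitudeWord = 1, amplitudeSyllable = 1,
                          amplitudeAm = 0, noiseSd = 0, eogSd = 0,
                          kernelWord = makeErpKernel("windowed_sine", 0.1, 0.4,
                                                     samplingRate = 128),
                          kernelSyllable = makeErpKernel("windowed_sine", 0.03,
                                                         0.18,
                                                         samplingRate = 128))
  rec <- simulateRecording(tl, cfg)
  raw <- averageAndSpectrum(cleanEpochs(rec, tl))
  filt <- averageAndSpectrum(suppressWarnings(preprocessRecording(rec, tl,
    doEogRegression = FALSE, doMask = FALSE, doReject = FALSE)))
  for (f in c(2, 4)) {
    i <- which.min(abs(frequencies(raw) - f))
    a0 <- Mod(spectralCoefficients(raw)[1, i])
    a1 <- Mod(spectralCoefficients(filt)[1, i])
    expect_lt(abs(a1 - a0) / a0, 0.02)
  }
})
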