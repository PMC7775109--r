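# Recording-to-trials chain: re-referencing, EOG regression, artifact
# masking, sentence-aware segmentation into fixed-length trials, rejection.

#' Re-reference scalp channels to the mastoid average
#'
#' Subtracts `(M1 + M2) / 2` from every scalp EEG channel. EOG channels are
#' bipolar derivations and are left untouched. Re-referencing twice is an
#' error.
#'
#' @param recording An [EEGRecording-class] with `M1` and `M2` channels and
#'   reference state `"raw"`.
#' @return The re-referenced recording (`referenceState = "mastoid_avg"`).
#' @export
rereferenceMastoids <- function(recording) {
  if (recording@referenceState != "raw")
    stop("recording is already re-referenced")
  if (!all(c("M1", "M2") %in% recording@channelLabels))
    stop("mastoid channels M1/M2 are missing")
  m1 <- match("M1", recording@channelLabels)
  m2 <- match("M2", recording@channelLabels)
  ref <- (recording@data[m1, ] + recording@data[m2, ]) / 2
  out <- recording
  eeg <- recording@channelRoles == "eeg"
  out@data[eeg, ] <- sweep(recording@data[eeg, , drop = FALSE], 2, ref)
  out@referenceState <- "mastoid_avg"
  out@provenance <- c(recording@provenance, "rereference")
  out
}

#' Regress ocular activity out of the scalp channels
#'
#' Least-squares regression of every scalp channel on HEOG and VEOG (plus an
#' intercept); the residuals replace the scalp data, so they are orthogonal
#' to both EOG channels. Constant (zero-variance) EOG channels are skipped
#' with a warning.
#'
#' @param recording An [EEGRecording-class] with HEOG and VEOG channels.
#' @return The cleaned recording. Estimated leakage coefficients are stored
#'   in `meta$eogBeta` (channels x regressors).
#' @export
regressOutEOG <- function(recording) {
  if (!all(c("HEOG", "VEOG") %in% recording@channelLabels))
    stop("EOG channels HEOG/VEOG are missing")
  h <- recording@data[match("HEOG", recording@channelLabels), ]
  v <- recording@data[match("VEOG", recording@channelLabels), ]
  keep <- c(sd(h) > 0, sd(v) > 0)
  if (!any(keep)) {
    warning("both EOG channels are constant; regression skipped")
    return(recording)
  }
  X <- cbind(intercept = 1, HEOG = h, VEOG = v)[, c(TRUE, keep), drop = FALSE]
  eeg <- which(recording@channelRoles == "eeg")
  Y <- t(recording@data[eeg, , drop = FALSE])
  beta <- qr.solve(qr(X), Y)                    # regressors x channels
  out <- recording
  out@data[eeg, ] <- t(Y - X %*% beta)
  out@meta$eogBeta <- t(beta)
  dimnames(out@meta$eogBeta) <- list(recording@channelLabels[eeg],
                                     colnames(X))
  out@provenance <- c(recording@provenance, "eog_regression")
  out
}

#' Mask large transient artifacts
#'
#' Marks every sample whose magnitude exceeds `threshold` (default 1000
#' microvolts = 1 mV) in the recording's mask; sample values are not altered.
#' Masked samples cause conservative trial rejection downstream rather than
#' interpolation.
#'
#' @param recording An [EEGRecording-class].
#' @param threshold Magnitude threshold in microvolts.
#' @return The recording with its `mask` slot filled.
#' @export
maskLargeArtifacts <- function(recording, threshold = 1000) {
  if (threshold <= 0) stop("threshold must be positive")
  out <- recording
  out@mask <- abs(recording@data) > threshold
  out@provenance <- c(recording@provenance, "mask_artifacts")
  out
}

# Per-sentence analysis windows: from the onset of the third syllable to the
# offset of the last syllable. Sentences shorter than three syllables
# contribute nothing.
.analysisWindows <- function(timeline) {
  ev <- timeline@events
  do.call(rbind, lapply(split(ev, ev$sentenceId), function(s) {
    if (nrow(s) < 3) return(NULL)
    data.frame(start = s$onset[3], end = s$onset[nrow(s)] + s$duration[nrow(s)])
  }))
}

#' Segment a recording into fixed-length trials
#'
#' Excises the inter-sentence gaps and the responses to the first two
#' syllables of every sentence (sound-onset responses), concatenates the
#' remaining per-sentence stretches, and cuts the concatenation into
#' consecutive `epochDuration`-second trials (a leftover tail shorter than
#' one trial is discarded). With isochronous timing every excised span is an
#' integer multiple of the 0.5-s word period, so the 2-Hz and 4-Hz phases are
#' continuous across the splices. Only scalp EEG channels are retained.
#'
#' @param recording A preprocessed [EEGRecording-class] aligned to the
#'   timeline (sample 0 at timeline time 0).
#' @param timeline The timed [SyllableTimeline-class] of the stimulus.
#' @param epochDuration Trial length in seconds (default 7).
#' @return An [EpochedResponse-class].
#' @export
segmentTrials <- function(recording, timeline, epochDuration = 7) {
  fs <- recording@samplingRate
  win <- .analysisWindows(timeline)
  if (is.null(win) || !nrow(win)) stop("timeline has no usable sentences")
  n <- ncol(recording@data)
  idx <- unlist(lapply(seq_len(nrow(win)), function(i) {
    i0 <- timeToSample(win$start[i], fs)
    i1 <- min(timeToSample(win$end[i], fs) - 1L, n - 1L)
    if (i0 > i1) return(integer(0))  # window lies past the recording end
    seq.int(i0, i1) + 1L
  }))
  eeg <- recording@channelRoles == "eeg"
  concat <- recording@data[eeg, idx, drop = FALSE]
  maskRow <- if (length(recording@mask))
    apply(recording@mask[, idx, drop = FALSE], 2, any) else
    rep(FALSE, length(idx))
  nPer <- as.integer(round(epochDuration * fs))
  nTr <- ncol(concat) %/% nPer
  if (nTr < 1) stop("concatenated response shorter than one trial (",
                    ncol(concat) / fs, " s < ", epochDuration, " s)")
  dat <- array(0, dim = c(nTr, sum(eeg), nPer))
  masked <- logical(nTr)
  for (t in seq_len(nTr)) {
    cols <- ((t - 1L) * nPer + 1L):(t * nPer)
    dat[t, , ] <- concat[, cols]
    masked[t] <- any(maskRow[cols])
  }
  new("EpochedResponse", data = dat, samplingRate = fs,
      epochDuration = epochDuration,
      channelLabels = recording@channelLabels[eeg],
      keptTrials = seq_len(nTr),
      rejectionLog = data.frame(trial = integer(0), reason = character(0)),
      trialMasked = masked,
      provenance = c(recording@provenance, "segment"))
}

#' Reject artifact trials
#'
#' Automated proxy for visual trial inspection: a trial is dropped when (a)
#' it contains masked samples, (b) its peak-to-peak amplitude on any channel
#' exceeds `ptpThreshold`, or (c) its mean channel variance exceeds
#' `varFactor` times the median across trials. Retained trials are returned
#' unaltered; dropped trials and reasons are logged.
#'
#' @param epochs An [EpochedResponse-class].
#' @param ptpThreshold Peak-to-peak threshold in microvolts (default 200).
#' @param varFactor Variance criterion multiplier (default 4).
#' @return The pruned [EpochedResponse-class].
#' @export
rejectTrials <- function(epochs, ptpThreshold = 200, varFactor = 4) {
  nTr <- dim(epochs@data)[1]
  if (nTr < 1) stop("no trials to inspect")
  ptp <- vapply(seq_len(nTr), function(t) {
    x <- epochs@data[t, , , drop = FALSE]
    max(apply(x[1, , , drop = TRUE], 1, function(r) diff(range(r))))
  }, numeric(1))
  v <- vapply(seq_len(nTr), function(t)
    mean(apply(epochs@data[t, , , drop = TRUE], 1, var)), numeric(1))
  reason <- rep(NA_character_, nTr)
  reason[v > varFactor * median(v)] <- "variance"
  reason[ptp > ptpThreshold] <- "peak_to_peak"
  reason[epochs@trialMasked] <- "masked_samples"
  drop <- !is.na(reason)
  if (all(drop)) stop("all trials rejected")
  out <- epochs
  out@data <- epochs@data[!drop, , , drop = FALSE]
  out@keptTrials <- epochs@keptTrials[!drop]
  out@trialMasked <- epochs@trialMasked[!drop]
  out@rejectionLog <- rbind(epochs@rejectionLog,
    data.frame(trial = epochs@keptTrials[drop], reason = reason[drop]))
  out@provenance <- c(epochs@provenance, "reject_trials")
  out
}

#' Run the full recording-to-trials preprocessing chain
#'
#' Applies, in order: downsampling to `targetRate`, mastoid re-referencing,
#' band-pass FIR filtering with delay compensation, EOG regression and
#' artifact masking, then sentence-aware segmentation and trial rejection.
#' Individual stages can be disabled for controlled analyses of noise-free
#' simulations.
#'
#' @param recording A raw [EEGRecording-class].
#' @param timeline The stimulus [SyllableTimeline-class].
#' @param targetRate Analysis sampling rate (default 128 Hz).
#' @param filterSpec A [FilterSpec-class], or `NULL` to design the default
#'   0.8-30 Hz filter at `targetRate`.
#' @param epochDuration Trial length in seconds.
#' @param doFilter,doEogRegression,doMask,doReject Stage switches.
#' @param ptpThreshold,varFactor Passed to [rejectTrials()].
#' @return An [EpochedResponse-class].
#' @export
preprocessRecording <- function(recording, timeline, targetRate = 128,
                                filterSpec = NULL, epochDuration = 7,
                                doFilter = TRUE, doEogRegression = TRUE,
                                doMask = TRUE, doReject = TRUE,
                                ptpThreshold = 200, varFactor = 4) {
  rec <- downsampleRecording(recording, targetRate)
  rec <- rereferenceMastoids(rec)
  if (doFilter) {
    if (is.null(filterSpec)) filterSpec <- designBandpassFIR(targetRate)
    rec <- applyFilterCompensated(rec, filterSpec)
  }
  if (doEogRegression) rec <- regressOutEOG(rec)
  if (doMask) rec <- maskLargeArtifacts(rec)
  epochs <- segmentTrials(rec, timeline, epochDuration)
  if (doReject) epochs <- rejectTrials(epochs, ptpThreshold, varFactor)
  epochs
}
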