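# Time-warping: convert responses to naturally timed syllables into a
# simulated response to isochronous 4-Hz presentation, s(t) = sum_j h_j(t)
# convolved with delta(t - 0.25 j), by overlap-adding each syllable's
# 0-750 ms response segment at its isochronous grid position.

#' Extract per-syllable response segments
#'
#' Slices the recording into one `[onset, onset + 0.75 s)` segment per
#' syllable. Natural syllables closer than 750 ms apart yield overlapping
#' windows, so samples can appear in consecutive segments. A syllable whose
#' window runs past the end of the recording keeps its grid slot but is
#' zero-filled and flagged (renumbering is disallowed so downstream 2-Hz
#' phase bookkeeping stays intact).
#'
#' @param recording An [EEGRecording-class].
#' @param timeline The timed [SyllableTimeline-class] aligned to the
#'   recording (sample 0 at time 0).
#' @return A [SyllableResponseSet-class].
#' @export
extractSyllableResponses <- function(recording, timeline) {
  if (timeline@timing == "none") stop("timeline has no timing")
  fs <- recording@samplingRate
  segLen <- as.integer(round(0.75 * fs))
  onsets <- timeline@events$onset
  n <- ncol(recording@data)
  nCh <- nrow(recording@data)
  seg <- array(0, dim = c(length(onsets), nCh, segLen))
  kept <- logical(length(onsets))
  for (j in seq_along(onsets)) {
    i0 <- timeToSample(onsets[j], fs) + 1L
    i1 <- i0 + segLen - 1L
    if (i1 <= n) {
      seg[j, , ] <- recording@data[, i0:i1]
      kept[j] <- TRUE
    }
  }
  new("SyllableResponseSet", segments = seg, kept = kept, samplingRate = fs,
      channelLabels = recording@channelLabels, timeline = timeline)
}

#' Warp syllable responses onto the isochronous 4-Hz grid
#'
#' Places the j-th response segment at the isochronous onset of syllable j
#' (0.25-s spacing within sentences; sentence gaps stay as silence slots,
#' mirroring the isochronous pipeline) and overlap-adds the 0.25-0.75 s
#' tails into the following slots, with no windowing or crossfade. The
#' result is returned as a [WarpedResponse-class] whose timeline has
#' isochronous timing, ready for [segmentTrials()] and the spectral module.
#'
#' @param responses A [SyllableResponseSet-class] with at least two syllables.
#' @return A [WarpedResponse-class].
#' @export
warpToIsochronous <- function(responses) {
  nSyl <- dim(responses@segments)[1]
  if (nSyl < 2) stop("need at least two syllables to warp")
  fs <- responses@samplingRate
  segLen <- dim(responses@segments)[3]
  isoTimeline <- assignIsochronousTiming(responses@timeline)
  onsets <- isoTimeline@events$onset
  n <- timeToSample(max(onsets), fs) + segLen
  nCh <- dim(responses@segments)[2]
  out <- matrix(0, nCh, n)
  for (j in seq_len(nSyl)) {
    if (!responses@kept[j]) next
    i0 <- timeToSample(onsets[j], fs) + 1L
    cols <- i0:(i0 + segLen - 1L)
    out[, cols] <- out[, cols] + responses@segments[j, , ]
  }
  src <- responses@timeline
  rec <- new("EEGRecording", data = out, samplingRate = fs,
             channelLabels = responses@channelLabels,
             channelRoles = rep("eeg", nCh),
             referenceState = "mastoid_avg",
             provenance = c("timewarp"),
             meta = list(sourceTiming = src@timing))
  new("WarpedResponse", recording = rec, timeline = isoTimeline)
}
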