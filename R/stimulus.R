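# Stimulus model: syllable/word timelines and amplitude envelopes.
#
# Narratives are built from sentences with an even number of syllables. In a
# metrical narrative each sentence is a sequence of "feet" of two syllables,
# where a foot is either one disyllabic word or a pair of monosyllabic words,
# so every odd-position (sigma1) syllable is a word onset and word onsets are
# periodic at half the syllable rate. Nonmetrical narratives place no such
# constraint and additionally require at least one sigma1 syllable per
# sentence that is not a word onset.

.SYL_DUR <- 0.25      # seconds
.GAP_DUR <- 0.5       # punctuation gap, the duration of two syllables

.newTimeline <- function(events, mode, timing = "none", condition = "none") {
  rownames(events) <- NULL
  new("SyllableTimeline", events = events, mode = mode, timing = timing,
      condition = condition)
}

.drawSentenceLengths <- function(nSyllables, sentenceLengths) {
  if (any(sentenceLengths %% 2 != 0) || any(sentenceLengths < 2))
    stop("sentence lengths must be even and >= 2")
  lens <- integer(0)
  total <- 0L
  while (total < nSyllables) {
    L <- sample(sentenceLengths, 1L)
    if (total + L > nSyllables) L <- as.integer(nSyllables - total)
    lens <- c(lens, L)
    total <- total + L
  }
  # A trimmed 2-syllable sentence cannot host a nonmetrical violation
  # (position 1 always starts a word); fold it into the previous sentence.
  k <- length(lens)
  if (k > 1L && lens[k] == 2L) {
    lens[k - 1L] <- lens[k - 1L] + 2L
    lens <- lens[-k]
  }
  lens
}

#' Generate a metrical syllable timeline
#'
#' Builds a narrative in which every odd-position (sigma1) syllable within a
#' sentence is the onset of a word: each two-syllable foot is either a
#' disyllabic word (with probability `pDisyllabic`) or a pair of monosyllabic
#' words. Timing is not yet assigned; see [assignIsochronousTiming()] and
#' [assignNaturalTiming()].
#'
#' @param nSyllables Total syllable count; must be even.
#' @param pDisyllabic Probability that a foot is a disyllabic word. The
#'   default 0.77 makes 77% of sigma2 syllables the second syllable of a
#'   disyllabic word; 0.73 is retained as the alternative published fraction.
#' @param sentenceLengths Even syllable counts sentences are drawn from
#'   (uniformly); the last sentence is trimmed to fit `nSyllables`.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @return A [SyllableTimeline-class] in metrical mode, timing `"none"`.
#' @examples
#' tl <- generateMetricalTimeline(200, seed = 1)
#' ev <- syllableEvents(tl)
#' all(ev$wordOnset[ev$parity == 1])  # sigma1 syllables are word onsets
#' @export
generateMetricalTimeline <- function(nSyllables, pDisyllabic = 0.77,
                                     sentenceLengths = seq(8L, 20L, 2L),
                                     seed = 1L) {
  if (nSyllables %% 2 != 0)
    stop("'nSyllables' must be even: metrical sentences pair syllables into ",
         "two-syllable feet, so an odd total cannot be tiled")
  if (pDisyllabic < 0 || pDisyllabic > 1) stop("'pDisyllabic' must be in [0, 1]")
  withSeed(seed, {
    lens <- .drawSentenceLengths(nSyllables, sentenceLengths)
    wordId <- 0L
    rows <- vector("list", length(lens))
    for (s in seq_along(lens)) {
      L <- lens[s]
      nFeet <- L %/% 2L
      disyl <- runif(nFeet) < pDisyllabic
      parity <- rep(c(1L, 2L), nFeet)
      wordOnset <- logical(L)
      wid <- integer(L)
      wlen <- integer(L)
      for (f in seq_len(nFeet)) {
        i1 <- 2L * f - 1L; i2 <- 2L * f
        if (disyl[f]) {
          wordId <- wordId + 1L
          wordOnset[i1] <- TRUE
          wid[c(i1, i2)] <- wordId
          wlen[c(i1, i2)] <- 2L
        } else {
          wordId <- wordId + 1L
          wordOnset[i1] <- TRUE; wid[i1] <- wordId; wlen[i1] <- 1L
          wordId <- wordId + 1L
          wordOnset[i2] <- TRUE; wid[i2] <- wordId; wlen[i2] <- 1L
        }
      }
      rows[[s]] <- data.frame(
        onset = NA_real_, duration = NA_real_, parity = parity,
        wordOnset = wordOnset, wordId = wid, wordLength = wlen,
        amplified = FALSE, sentenceId = s,
        gapAfter = c(rep(FALSE, L - 1L), TRUE))
    }
    .newTimeline(do.call(rbind, rows), mode = "metrical")
  })
}

#' Generate a nonmetrical syllable timeline
#'
#' Packs words of random length (1 or 2 syllables) into even-length sentences
#' with no parity constraint, requiring at least one odd-position syllable per
#' sentence that is not a word onset. Word onsets therefore carry no 2-Hz
#' periodicity.
#'
#' @param nSyllables Total syllable count; must be even.
#' @param wordLengthProb Named numeric: probabilities of word lengths `"1"`
#'   and `"2"`. A zero probability of disyllabic words makes the constraint
#'   unsatisfiable (every syllable is then a word onset) and is an error.
#' @param sentenceLengths Even sentence lengths drawn uniformly.
#' @param seed Integer seed.
#' @param maxRetries Bounded retries per sentence before giving up.
#' @return A [SyllableTimeline-class] in nonmetrical mode, timing `"none"`.
#' @export
generateNonmetricalTimeline <- function(nSyllables,
                                        wordLengthProb = c("1" = 0.4, "2" = 0.6),
                                        sentenceLengths = seq(8L, 20L, 2L),
                                        seed = 1L, maxRetries = 100L) {
  if (nSyllables %% 2 != 0) stop("'nSyllables' must be even")
  p2 <- unname(wordLengthProb["2"])
  if (is.na(p2)) p2 <- 0
  withSeed(seed, {
    lens <- .drawSentenceLengths(nSyllables, sentenceLengths)
    wordId <- 0L
    rows <- vector("list", length(lens))
    for (s in seq_along(lens)) {
      L <- lens[s]
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        if (attempt > maxRetries)
          stop("could not satisfy the nonmetrical constraint (>= 1 odd-position ",
               "non-onset per sentence) after ", maxRetries, " retries; ",
               "the word-length distribution may exclude disyllabic words")
        wl <- integer(0)
        while (sum(wl) < L) {
          len <- if (runif(1) < p2) 2L else 1L
          if (sum(wl) + len > L) len <- 1L  # close out the sentence
          wl <- c(wl, len)
        }
        pos <- cumsum(c(1L, wl[-length(wl)]))  # word start positions
        wordOnset <- seq_len(L) %in% pos
        # sigma1 syllables sit at odd positions; need one that is not an onset
        if (any(!wordOnset[seq(1L, L, 2L)])) break
      }
      wid <- rep(seq_along(wl) + wordId, times = wl)
      wlen <- rep(wl, times = wl)
      wordId <- wordId + length(wl)
      rows[[s]] <- data.frame(
        onset = NA_real_, duration = NA_real_,
        parity = rep(c(1L, 2L), L %/% 2L),
        wordOnset = wordOnset, wordId = wid, wordLength = wlen,
        amplified = FALSE, sentenceId = s,
        gapAfter = c(rep(FALSE, L - 1L), TRUE))
    }
    .newTimeline(do.call(rbind, rows), mode = "nonmetrical")
  })
}

#' Assign isochronous 4-Hz timing to a timeline
#'
#' All syllables get duration 0.250 s; within a sentence consecutive onsets
#' are 0.250 s apart, and a 0.500 s silence (punctuation gap, the duration of
#' two syllables) follows the last syllable of each sentence, so onsets
#' straddling a gap are 0.750 s apart. The first syllable starts at t = 0.
#'
#' @param timeline A [SyllableTimeline-class].
#' @return The timeline with timing `"isochronous"`.
#' @export
assignIsochronousTiming <- function(timeline) {
  ev <- timeline@events
  n <- nrow(ev)
  step <- rep(.SYL_DUR, n)
  step[which(ev$gapAfter)] <- .SYL_DUR + .GAP_DUR
  ev$onset <- cumsum(c(0, step[-n]))
  ev$duration <- .SYL_DUR
  .newTimeline(ev, mode = timeline@mode, timing = "isochronous",
               condition = timeline@condition)
}

# Truncated log-normal syllable-duration model for natural speech: support
# [0.075, 0.354] s, mean 0.224 s (the range and mean of the synthesised
# syllable inventory). sdlog fixed; meanlog solved so the truncated mean hits
# the target.
.naturalDurationParams <- function(a = 0.075, b = 0.354, target = 0.224,
                                   sdlog = 0.25) {
  truncMean <- function(mu) {
    za <- (log(a) - mu) / sdlog; zb <- (log(b) - mu) / sdlog
    exp(mu + sdlog^2 / 2) *
      (pnorm(zb - sdlog) - pnorm(za - sdlog)) / (pnorm(zb) - pnorm(za))
  }
  mu <- uniroot(function(m) truncMean(m) - target,
                lower = log(a), upper = log(b), tol = 1e-12)$root
  list(meanlog = mu, sdlog = sdlog, a = a, b = b)
}

#' Default natural syllable-duration sampler
#'
#' Draws durations from a log-normal distribution truncated to
#' \[0.075, 0.354\] s with mean 0.224 s, matching the duration range and mean
#' of synthesised Mandarin syllables.
#'
#' @param n Number of durations to draw.
#' @return Numeric vector of durations in seconds.
#' @export
rNaturalSyllableDuration <- local({
  cache <- NULL
  function(n) {
    if (is.null(cache)) cache <<- .naturalDurationParams()
    lo <- plnorm(cache$a, cache$meanlog, cache$sdlog)
    hi <- plnorm(cache$b, cache$meanlog, cache$sdlog)
    qlnorm(runif(n, lo, hi), cache$meanlog, cache$sdlog)
  }
})

#' Assign natural (jittered) timing to a timeline
#'
#' Syllable durations are drawn from `durationSampler` (non-positive draws are
#' resampled); onsets accumulate so each syllable starts when the previous one
#' ends, with the 0.500 s punctuation gap still inserted after sentence-final
#' syllables. A degenerate sampler returning 0.250 s reproduces isochronous
#' timing.
#'
#' @param timeline A [SyllableTimeline-class].
#' @param durationSampler `function(n)` returning `n` durations in seconds;
#'   defaults to [rNaturalSyllableDuration()].
#' @param seed Integer seed (determinism contract: same seed, same timeline).
#' @return The timeline with timing `"natural"`.
#' @export
assignNaturalTiming <- function(timeline,
                                durationSampler = rNaturalSyllableDuration,
                                seed = 1L) {
  ev <- timeline@events
  n <- nrow(ev)
  withSeed(seed, {
    dur <- durationSampler(n)
    for (i in 1:100) {
      bad <- !is.finite(dur) | dur <= 0
      if (!any(bad)) break
      dur[bad] <- durationSampler(sum(bad))
    }
    if (any(!is.finite(dur) | dur <= 0))
      stop("duration sampler kept returning non-positive durations")
    step <- dur + ifelse(ev$gapAfter, .GAP_DUR, 0)
    ev$onset <- cumsum(c(0, step[-n]))
    ev$duration <- dur
    .newTimeline(ev, mode = timeline@mode, timing = "natural",
                 condition = timeline@condition)
  })
}

#' Apply an amplitude-modulation condition
#'
#' Sets the amplified flags on exactly the sigma1 syllables
#' (`"sigma1"` condition), exactly the sigma2 syllables (`"sigma2"`), or none.
#' With isochronous metrical timing the amplified-syllable onset train is then
#' periodic at 2 Hz within sentences, and the sigma2-amplified train is the
#' sigma1-amplified train delayed by 0.250 s.
#'
#' @param timeline A [SyllableTimeline-class] with parity labels.
#' @param condition `"none"`, `"sigma1"` or `"sigma2"`.
#' @return The timeline with amplified flags and condition set.
#' @export
applyAmplitudeCondition <- function(timeline,
                                    condition = c("none", "sigma1", "sigma2")) {
  condition <- match.arg(condition)
  ev <- timeline@events
  ev$amplified <- switch(condition,
    none = rep(FALSE, nrow(ev)),
    sigma1 = ev$parity == 1L,
    sigma2 = ev$parity == 2L)
  .newTimeline(ev, mode = timeline@mode, timing = timeline@timing,
               condition = condition)
}

#' Render the stimulus amplitude envelope
#'
#' Each syllable contributes a unit-amplitude segment over
#' `[onset, onset + duration)`, scaled by 4 when amplified; the last 25 ms of
#' every syllable taper monotonically to zero under a raised-cosine window;
#' silence (gaps) is exactly zero. Only the amplitude envelope is rendered;
#' carrier fine structure is not modelled.
#'
#' @param timeline A timed [SyllableTimeline-class].
#' @param samplingRate Hz; must be at least 80 Hz so the 25-ms taper spans
#'   at least two samples.
#' @return A [StimulusEnvelope-class].
#' @export
renderEnvelope <- function(timeline, samplingRate) {
  if (timeline@timing == "none") stop("assign timing before rendering")
  if (samplingRate < 80)
    stop("samplingRate below 80 Hz cannot represent the 25-ms offset taper")
  ev <- timeline@events
  n <- ceiling((max(ev$onset + ev$duration)) * samplingRate) + 1L
  env <- numeric(n)
  taper <- 0.025
  for (i in seq_len(nrow(ev))) {
    i0 <- timeToSample(ev$onset[i], samplingRate)
    i1 <- timeToSample(ev$onset[i] + ev$duration[i], samplingRate) - 1L
    idx <- i0:i1
    t <- (idx - i0) / samplingRate
    amp <- if (ev$amplified[i]) 4 else 1
    seg <- rep(amp, length(idx))
    inTaper <- t >= ev$duration[i] - taper
    u <- (t[inTaper] - (ev$duration[i] - taper)) / taper
    seg[inTaper] <- amp * 0.5 * (1 + cos(pi * u))
    env[idx + 1L] <- seg
  }
  new("StimulusEnvelope", samples = env, samplingRate = samplingRate)
}

#' Onset times of event classes in a timeline
#'
#' Convenience extractor for the impulse-train views of a timeline: all
#' syllable onsets, word onsets only, or amplified-syllable onsets only.
#'
#' @param timeline A timed [SyllableTimeline-class].
#' @param type `"syllable"`, `"word"` or `"amplified"`.
#' @return Numeric vector of onset times in seconds.
#' @export
eventOnsets <- function(timeline, type = c("syllable", "word", "amplified")) {
  type <- match.arg(type)
  ev <- timeline@events
  switch(type,
    syllable = ev$onset,
    word = ev$onset[ev$wordOnset],
    amplified = ev$onset[ev$amplified])
}
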