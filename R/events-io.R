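# BIDS-style events TSV serialisation of syllable timelines.

#' Write a timeline as a BIDS-style events TSV
#'
#' Columns: `onset`, `duration` (seconds, 6 decimal places), `trial_type`
#' (`s1`/`s2`, the odd/even syllable parity), `word_onset` (0/1), `word_id`,
#' `amplified` (0/1), `sentence_id`.
#'
#' @param timeline A timed [SyllableTimeline-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeEventsTSV <- function(timeline, path) {
  if (timeline@timing == "none")
    stop("assign timing before serialising events")
  ev <- timeline@events
  out <- data.frame(
    onset = sprintf("%.6f", ev$onset),
    duration = sprintf("%.6f", ev$duration),
    trial_type = paste0("s", ev$parity),
    word_onset = as.integer(ev$wordOnset),
    word_id = ev$wordId,
    amplified = as.integer(ev$amplified),
    sentence_id = ev$sentenceId)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV back into a timeline
#'
#' Inverse of [writeEventsTSV()]. Word lengths and the punctuation-gap flags
#' are reconstructed from word ids and sentence boundaries; the mode is
#' inferred from whether every odd-parity syllable is a word onset.
#'
#' @param path Events TSV path.
#' @param timing Timing label to record (`"isochronous"` or `"natural"`);
#'   inferred from onset spacing when `NULL`.
#' @return A [SyllableTimeline-class].
#' @export
readEventsTSV <- function(path, timing = NULL) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  parity <- as.integer(sub("^s", "", tab$trial_type))
  n <- nrow(tab)
  wordLength <- as.integer(ave(rep(1L, n), tab$word_id, FUN = sum))
  gapAfter <- c(tab$sentence_id[-1] != tab$sentence_id[-n], TRUE)
  ev <- data.frame(
    onset = tab$onset, duration = tab$duration, parity = parity,
    wordOnset = tab$word_onset == 1L, wordId = tab$word_id,
    wordLength = wordLength, amplified = tab$amplified == 1L,
    sentenceId = tab$sentence_id, gapAfter = gapAfter)
  mode <- if (all(ev$wordOnset[ev$parity == 1L])) "metrical" else "nonmetrical"
  condition <- if (!any(ev$amplified)) "none"
    else if (all(ev$amplified == (ev$parity == 1L))) "sigma1"
    else "sigma2"
  if (is.null(timing)) {
    within <- diff(ev$onset)[!ev$gapAfter[-n]]
    timing <- if (all(abs(within - 0.25) < 1e-6)) "isochronous" else "natural"
  }
  new("SyllableTimeline", events = ev, mode = mode, timing = timing,
      condition = condition)
}
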