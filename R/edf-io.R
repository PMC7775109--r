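# Minimal EDF (European Data Format, 16-bit) writer and reader for
# exchanging recordings with standard EEG tooling. One-second data records;
# the final partial second is zero-padded on write and trimmed on read using
# the true sample count stored in the reserved header field.

.edfPad <- function(x, width) {
  s <- substr(x, 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records and per-channel physical scaling
#' (physical range = observed data range). Channel roles are encoded in the
#' labels; seed/config metadata should be kept in the JSON sidecar (see
#' [writeRecordingSidecar()]).
#'
#' @param recording An [EEGRecording-class] with an integer sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(recording, path) {
  fs <- recording@samplingRate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(fs)
  dat <- recording@data
  nCh <- nrow(dat)
  n <- ncol(dat)
  nRec <- as.integer(ceiling(n / fs))
  if (nRec * fs > n)
    dat <- cbind(dat, matrix(0, nCh, nRec * fs - n))
  physMin <- apply(dat, 1, min)
  physMax <- apply(dat, 1, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMin[flat] + 1
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdrBytes <- 256L + 256L * nCh
  writeChar(paste0(
    .edfPad("0", 8), .edfPad("X X X X", 80), .edfPad("Startdate X X X X", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfPad(as.character(hdrBytes), 8),
    .edfPad(paste0("nsamples=", n), 44),
    .edfPad(as.character(nRec), 8), .edfPad("1", 8),
    .edfPad(as.character(nCh), 4)), con, eos = NULL)
  field <- function(values, width)
    writeChar(paste(vapply(values, .edfPad, "", width = width),
                    collapse = ""), con, eos = NULL)
  field(recording@channelLabels, 16)
  field(rep("AgAgCl electrode", nCh), 80)
  field(rep("uV", nCh), 8)
  field(sprintf("%.6g", physMin), 8)
  field(sprintf("%.6g", physMax), 8)
  field(rep(as.character(digMin), nCh), 8)
  field(rep(as.character(digMax), nCh), 8)
  field(rep("", nCh), 80)
  field(rep(as.character(fs), nCh), 8)
  field(rep("", nCh), 32)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (c in seq_len(nCh)) {
      dig <- round((dat[c, cols] - physMin[c]) / scale[c]) + digMin
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads 16-bit EDF written by [writeEDF()] (or any EDF with a uniform
#' per-channel sampling rate). Channel roles are inferred from the labels
#' (HEOG/VEOG -> eog, M1/M2 -> mastoid, otherwise eeg).
#'
#' @param path EDF file path.
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  reserved <- rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  labels <- vapply(seq_len(nCh), function(i) rd(16), "")
  rd(80 * nCh); rd(8 * nCh)
  physMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8), ""))
  rd(80 * nCh)
  sampPerRec <- as.integer(vapply(seq_len(nCh), function(i) rd(8), ""))
  rd(32 * nCh)
  if (length(unique(sampPerRec)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- sampPerRec[1] / recDur
  dat <- matrix(0, nCh, nRec * sampPerRec[1])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    for (c in seq_len(nCh)) {
      dig <- readBin(con, "integer", sampPerRec[c], size = 2, signed = TRUE,
                     endian = "little")
      cols <- ((r - 1L) * sampPerRec[c] + 1L):(r * sampPerRec[c])
      dat[c, cols] <- (dig - digMin[c]) * scale[c] + physMin[c]
    }
  }
  if (grepl("^nsamples=", reserved)) {
    nTrue <- as.integer(sub("^nsamples=", "", reserved))
    if (is.finite(nTrue) && nTrue <= ncol(dat))
      dat <- dat[, seq_len(nTrue), drop = FALSE]
  }
  roles <- ifelse(labels %in% c("HEOG", "VEOG"), "eog",
           ifelse(labels %in% c("M1", "M2"), "mastoid", "eeg"))
  new("EEGRecording", data = dat, samplingRate = fs, channelLabels = labels,
      channelRoles = roles, referenceState = "raw",
      provenance = "read_edf", meta = list(path = path))
}

#' Write the JSON sidecar of a simulated recording
#'
#' Stores the simulation seed, condition tag and a hash of the configuration
#' next to an exported EDF, BIDS-style.
#'
#' @param recording An [EEGRecording-class] (typically simulated).
#' @param path Sidecar path (conventionally the EDF path with `.json`).
#' @param config Optional [SimulationConfig-class] to hash.
#' @return `path`, invisibly.
#' @export
writeRecordingSidecar <- function(recording, path, config = NULL) {
  meta <- list(
    samplingRate = recording@samplingRate,
    seed = recording@meta$seed,
    condition = recording@meta$condition,
    referenceState = recording@referenceState,
    provenance = recording@provenance)
  if (!is.null(config)) {
    ser <- serialize(config, NULL)
    meta$configHash <- sprintf("%08x", sum(as.integer(ser) *
      (seq_along(ser) %% 97 + 1)) %% .Machine$integer.max)
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
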