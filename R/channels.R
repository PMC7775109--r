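# Electrode montage constants and default topographic weight maps.

#' Standard 64-channel scalp montage
#'
#' Labels of the 64 scalp electrodes (10-20 system extension used by 64-channel
#' active-electrode caps, including FCz, Fz, Cz, FC3 and FC4), in cap order.
#'
#' @return Character vector of 64 electrode labels.
#' @export
scalpChannels64 <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

.AUX_CHANNELS <- c("HEOG", "VEOG", "M1", "M2")
.AUX_ROLES <- c(HEOG = "eog", VEOG = "eog", M1 = "mastoid", M2 = "mastoid")

#' Topographic weight presets
#'
#' Per-channel weight maps (maximum absolute weight 1) used as ground-truth
#' component topographies in simulations. `"centrofrontal"` peaks at FCz
#' (typical of auditory evoked responses measured against mastoids),
#' `"temporal"` peaks at T7/T8, `"uniform"` is flat.
#'
#' @param preset One of `"centrofrontal"`, `"temporal"`, `"uniform"`.
#' @param channels Channel labels the map is defined over.
#' @return Named numeric vector of weights with `max(abs(weights)) == 1`.
#' @export
topographyPreset <- function(preset = c("centrofrontal", "temporal", "uniform"),
                             channels = scalpChannels64()) {
  preset <- match.arg(preset)
  w <- setNames(rep(0.2, length(channels)), channels)
  ring <- function(labels, value) {
    hit <- intersect(labels, channels)
    w[hit] <<- value
  }
  if (preset == "centrofrontal") {
    ring("FCz", 1)
    ring(c("Fz", "Cz", "FC1", "FC2"), 0.9)
    ring(c("FC3", "FC4", "C1", "C2", "F1", "F2"), 0.7)
    ring(c("C3", "C4", "F3", "F4", "CPz", "AFz", "CP1", "CP2"), 0.5)
    ring(c("C5", "C6", "F5", "F6", "CP3", "CP4", "FC5", "FC6"), 0.35)
  } else if (preset == "temporal") {
    ring(c("T7", "T8"), 1)
    ring(c("TP7", "TP8", "FT7", "FT8"), 0.8)
    ring(c("C5", "C6", "CP5", "CP6", "FC5", "FC6"), 0.6)
    ring(c("P7", "P8", "F7", "F8"), 0.4)
  } else {
    w[] <- 1
  }
  w / max(abs(w))
}

# Default ocular leakage gains: strongest over prefrontal sites, decaying
# toward central electrodes, zero posteriorly.
defaultEogGain <- function(channels = scalpChannels64(), scale = 0.15) {
  g <- setNames(rep(0, length(channels)), channels)
  set <- function(labels, value) {
    hit <- intersect(labels, channels)
    g[hit] <<- value
  }
  set(c("Fp1", "Fp2", "Fpz"), 1)
  set(c("AF7", "AF8", "AF3", "AF4", "AFz"), 0.7)
  set(c("F7", "F8", "F5", "F6", "F3", "F4", "F1", "F2", "Fz"), 0.4)
  set(c("FT7", "FT8", "FC5", "FC6", "FC3", "FC4", "FC1", "FC2", "FCz"), 0.15)
  g * scale
}
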