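## Standard 10-10 labels for the 60-channel scalp montage, frontal to
## occipital. The medial centro-parietal set reported to carry coherent
## power patterns in both team roles is a subset of these labels.
MONTAGE60 <- c(
  "Fp1", "Fpz", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "O2")

#' Medial centro-parietal electrode set
#'
#' The eleven midline/para-midline centro-parietal electrodes used by default
#' for the inter-subject frequency-correlation analysis.
#' @return character vector of channel labels
#' @export
centro_parietal_set <- function() {
  c("C1", "Cz", "C2", "CP1", "CPz", "CP2", "P3", "P1", "Pz", "P2", "POz")
}

#' Default scalp montage labels
#'
#' Returns `k` scalp channel labels. For `k = 60` this is the full 10-10
#' montage. For reduced montages (used for desk-scale simulations) the
#' centro-parietal set is retained first so that the power-pattern analyses
#' remain applicable, and remaining labels fill up in montage order.
#' @param k number of scalp electrodes per subject (1..60)
#' @return character vector of length `k`
#' @export
default_montage <- function(k = 60) {
  stopifnot(k >= 1, k <= length(MONTAGE60))
  if (k == length(MONTAGE60)) return(MONTAGE60)
  cp <- centro_parietal_set()
  if (k <= length(cp)) return(cp[seq_len(k)])
  c(cp, setdiff(MONTAGE60, cp)[seq_len(k - length(cp))])
}
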