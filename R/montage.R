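#' Default 64-channel 10-20 montage
#'
#' Ordered channel labels of the whole-head 64-channel extended 10-20 layout
#' assumed by the default configuration. It contains the six peripheral
#' channels (M1, M2, TP9, TP10, PO9, PO10) that the pipeline excludes before
#' decoding, leaving 58 analysis channels.
#'
#' @return character vector of 64 unique channel labels.
#' @export
default_montage <- function() {
  c(
    "Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "M1", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "M2",
    "TP9", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "PO4", "PO8", "PO10",
    "O1", "Oz", "O2"
  )
}

#' Peripheral channels excluded from decoding
#'
#' The six scalp-edge channels most affected by muscular artifacts, dropped
#' before lag embedding.
#'
#' @return character vector of 6 labels.
#' @export
peripheral_channels <- function() c("M1", "M2", "TP9", "TP10", "PO9", "PO10")

#' Frontal channels used in the ocular-artifact control
#'
#' The four frontal channels most affected by eye blinks and eye movements.
#' Re-running the decoder without them is the standard control for
#' artifact-driven decoding.
#'
#' @return character vector of 4 labels.
#' @export
frontal_channels <- function() c("Fp1", "Fp2", "AF7", "AF8")

#' Default scalp region-of-interest map
#'
#' Partition of the 58 retained channels into 8 named scalp regions used as
#' feature blocks by the multiple-kernel grasp classifier: left/right frontal
#' (LF/RF), temporal (LT/RT), sensorimotor (LSM/RSM) and parietal-occipital
#' (LPO/RPO). Midline channels are deliberately unassigned. The map is plain
#' configuration and can be overridden wholesale.
#'
#' @return named list mapping region name to a character vector of labels.
#' @export
default_roi_map <- function() {
  list(
    LF  = c("Fp1", "AF7", "AF3", "F7", "F5", "F3", "F1"),
    RF  = c("Fp2", "AF8", "AF4", "F8", "F6", "F4", "F2"),
    LT  = c("FT7", "T7", "TP7"),
    RT  = c("FT8", "T8", "TP8"),
    LSM = c("FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1"),
    RSM = c("FC6", "FC4", "FC2", "C6", "C4", "C2", "CP6", "CP4", "CP2"),
    LPO = c("P7", "P5", "P3", "P1", "PO7", "PO3", "O1"),
    RPO = c("P8", "P6", "P4", "P2", "PO8", "PO4", "O2")
  )
}

validate_roi_map <- function(roi_map, channel_labels = NULL) {
  if (!is.list(roi_map) || is.null(names(roi_map)) || any(!nzchar(names(roi_map)))) {
    stopf("roi_map must be a named list of channel-label vectors")
  }
  all_ch <- unlist(roi_map, use.names = FALSE)
  if (anyDuplicated(all_ch)) stopf("ROI regions must be disjoint")
  if (any(lengths(roi_map) == 0)) stopf("every ROI must contain at least one channel")
  if (!is.null(channel_labels)) {
    missing <- setdiff(all_ch, channel_labels)
    if (length(missing)) {
      stopf("ROI channels not present in the recording: %s",
            paste(missing, collapse = ", "))
    }
  }
  invisible(roi_map)
}

#' Default hand joint labels
#'
#' The 15 joint angles retained for analysis: thumb carpo-metacarpal (CMC),
#' metacarpo-phalangeal (MCP) and inter-phalangeal (IP); MCP and proximal
#' inter-phalangeal (PIP) of the four fingers; and the four abduction (ABD)
#' angles between digits.
#'
#' @return character vector of 15 labels.
#' @export
default_joint_labels <- function() {
  c(
    "thumb_CMC", "thumb_MCP", "thumb_IP",
    "index_MCP", "index_PIP", "middle_MCP", "middle_PIP",
    "ring_MCP", "ring_PIP", "little_MCP", "little_PIP",
    "ABD_thumb_index", "ABD_index_middle", "ABD_middle_ring", "ABD_ring_little"
  )
}

#' Grasped objects of the five-class task
#' @return character vector of the 5 object labels.
#' @export
object_labels <- function() c("can", "card", "cd", "penny", "screwdriver")
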