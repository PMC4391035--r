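#' Construct a synchronized EEG/kinematics recording
#'
#' The central data container: continuous multichannel EEG (microvolts),
#' optionally synchronized joint-angle time series (degrees), a shared
#' sampling rate, and trial event markers. EEG and kinematics must share the
#' sample count. Sample indices are 1-based and trial intervals are
#' inclusive.
#'
#' @param eeg numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names, one per
#'   EEG row (10-20 names for real recordings).
#' @param kin optional numeric matrix, joints x samples (degrees), sample-
#'   aligned with `eeg`.
#' @param joint_labels character vector of joint names; must have exactly 15
#'   entries when kinematics are present.
#' @param events optional data.frame with columns `onset`, `offset` (1-based
#'   sample indices, onset < offset, both within the recording) and `label`
#'   (grasped object).
#' @return an object of class `grasp_recording`.
#' @export
recording <- function(eeg, fs, channel_labels, kin = NULL, joint_labels = NULL,
                      events = NULL) {
  eeg <- as.matrix(eeg)
  channel_labels <- unname(as.character(channel_labels))
  if (!is.null(joint_labels)) joint_labels <- unname(as.character(joint_labels))
  if (!is.numeric(eeg)) stopf("eeg must be numeric")
  if (length(channel_labels) != nrow(eeg)) {
    stopf("channel_labels length (%d) != EEG channel count (%d)",
          length(channel_labels), nrow(eeg))
  }
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be a positive scalar")
  if (!is.null(kin)) {
    kin <- as.matrix(kin)
    if (ncol(kin) != ncol(eeg)) {
      stopf("alignment error: EEG has %d samples but kinematics has %d",
            ncol(eeg), ncol(kin))
    }
    if (is.null(joint_labels)) joint_labels <- default_joint_labels()
    if (length(joint_labels) != 15L || nrow(kin) != 15L) {
      stopf("kinematics must carry exactly 15 labelled joints (got %d rows, %d labels)",
            nrow(kin), length(joint_labels))
    }
    rownames(kin) <- joint_labels
  }
  rownames(eeg) <- channel_labels
  if (!is.null(events)) events <- validate_events(events, ncol(eeg))
  structure(
    list(eeg = eeg, kin = kin, fs = fs,
         channel_labels = as.character(channel_labels),
         joint_labels = if (is.null(kin)) NULL else as.character(joint_labels),
         events = events),
    class = "grasp_recording"
  )
}

validate_events <- function(events, n_samples) {
  events <- as.data.frame(events)
  need <- c("onset", "offset", "label")
  if (!all(need %in% names(events))) {
    stopf("events must have columns onset, offset, label")
  }
  events <- data.frame(onset = as.integer(unname(unlist(events$onset))),
                       offset = as.integer(unname(unlist(events$offset))),
                       label = as.character(unname(unlist(events$label))))
  bad <- events$onset >= events$offset | events$onset < 1L | events$offset > n_samples
  if (any(bad)) {
    stopf("%d event(s) have onset >= offset or fall outside the recording", sum(bad))
  }
  events
}

#' @export
print.grasp_recording <- function(x, ...) {
  cat(sprintf("<grasp_recording> %d EEG channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$eeg), ncol(x$eeg), x$fs, ncol(x$eeg) / x$fs))
  if (!is.null(x$kin)) cat(sprintf("  kinematics: %d joints\n", nrow(x$kin)))
  if (!is.null(x$events)) {
    cat(sprintf("  events: %d trials (%s)\n", nrow(x$events),
                paste(sprintf("%s:%d", names(table(x$events$label)),
                              as.integer(table(x$events$label))), collapse = ", ")))
  }
  invisible(x)
}

n_samples <- function(rec) ncol(rec$eeg)

CONTAINER_VERSION <- "1.0"

#' Write a recording to disk
#'
#' `format = "csv"` writes the package's versioned plain-text container: a
#' directory holding `eeg.csv` / `kin.csv` (one column per channel, header
#' row of labels), `events.csv` and `meta.json`. `format = "brainvision"`
#' writes a BrainVision triplet (.vhdr/.eeg/.vmrk, IEEE float32, EEG and
#' markers only); `format = "edf"` a 16-bit EDF (EEG only, quantized to the
#' per-channel physical range).
#'
#' @param rec a [recording()].
#' @param path directory (csv) or file stem (brainvision/edf).
#' @param format one of `"csv"`, `"brainvision"`, `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("csv", "brainvision", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "grasp_recording"))
  switch(format,
    csv = write_recording_csv(rec, path),
    brainvision = write_brainvision(rec, path),
    edf = write_edf(rec, path)
  )
  invisible(path)
}

write_recording_csv <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  eeg <- as.data.frame(t(rec$eeg))
  names(eeg) <- rec$channel_labels
  data.table::fwrite(eeg, file.path(path, "eeg.csv"))
  if (!is.null(rec$kin)) {
    kin <- as.data.frame(t(rec$kin))
    names(kin) <- rec$joint_labels
    data.table::fwrite(kin, file.path(path, "kin.csv"))
  }
  if (!is.null(rec$events)) {
    data.table::fwrite(rec$events, file.path(path, "events.csv"))
  }
  meta <- list(container_version = CONTAINER_VERSION, fs = rec$fs,
               channel_labels = rec$channel_labels,
               joint_labels = rec$joint_labels)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. For `format = "csv"`, `path` may be
#' either the container directory or a single delimited file of EEG (one
#' column per channel, header row of labels), in which case `fs` must be
#' given.
#'
#' @param path container directory, single CSV file, `.vhdr` file, or `.edf`
#'   file.
#' @param format one of `"csv"`, `"brainvision"`, `"edf"`.
#' @param fs sampling rate, required only for a bare CSV file.
#' @param marker_map for BrainVision markers: a user-supplied dictionary
#'   mapping marker description to its role, see [read_brainvision()].
#'   Vendor marker semantics are never guessed.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("csv", "brainvision", "edf"),
                           fs = NULL, marker_map = NULL) {
  format <- match.arg(format)
  switch(format,
    csv = read_recording_csv(path, fs),
    brainvision = read_brainvision(path, marker_map),
    edf = read_edf(path)
  )
}

read_recording_csv <- function(path, fs = NULL) {
  if (dir.exists(path)) {
    meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
    meta$fs <- as.numeric(meta$fs)
    eeg <- t(as.matrix(data.table::fread(file.path(path, "eeg.csv"))))
    kin <- NULL
    if (file.exists(file.path(path, "kin.csv"))) {
      kin <- t(as.matrix(data.table::fread(file.path(path, "kin.csv"))))
    }
    events <- NULL
    if (file.exists(file.path(path, "events.csv"))) {
      events <- as.data.frame(data.table::fread(file.path(path, "events.csv")))
    }
    recording(eeg, fs = meta$fs, channel_labels = meta$channel_labels,
              kin = kin, joint_labels = meta$joint_labels, events = events)
  } else {
    if (!file.exists(path)) stopf("no such file or directory: %s", path)
    if (is.null(fs)) stopf("fs must be supplied when reading a bare CSV file")
    tab <- data.table::fread(path)
    recording(t(as.matrix(tab)), fs = fs, channel_labels = names(tab))
  }
}
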