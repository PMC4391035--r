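# Minimal BrainVision (.vhdr/.eeg/.vmrk) support: multiplexed IEEE float32
# binary, microvolt units. Covers what the pipeline needs (continuous EEG +
# markers); vendor marker semantics are never guessed -- mapping marker
# descriptions to trial onset/offset/object is user configuration.

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header, the binary `.eeg` data (multiplexed IEEE
#' float32 or int16, per-channel resolution applied) and the `.vmrk` marker
#' file. Markers are turned into trial events through `marker_map`:
#' `marker_map$onsets` is a named character vector mapping an onset marker
#' description to its object label, `marker_map$offsets` a character vector
#' of offset descriptions; an onset opens a trial, the next offset closes
#' it. With `marker_map = NULL` the scheme used by [write_recording()]
#' (`"onset:<label>"` / `"offset"`) is assumed.
#'
#' @param path path to the `.vhdr` file.
#' @param marker_map marker dictionary as described above, or `NULL`.
#' @return a [recording()] (EEG and events only).
#' @export
read_brainvision <- function(path, marker_map = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  hdr <- parse_bv_ini(readLines(path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  if (!identical(toupper(ci$DataFormat %||% "BINARY"), "BINARY") ||
      !identical(toupper(ci$DataOrientation %||% "MULTIPLEXED"), "MULTIPLEXED")) {
    stopf("only BINARY MULTIPLEXED BrainVision data are supported")
  }
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  chans <- hdr[["Channel Infos"]]
  ord <- order(as.integer(sub("^Ch", "", names(chans))))
  chans <- chans[ord]
  parts <- lapply(chans, function(v) strsplit(v, ",")[[1]])
  labels <- vapply(parts, `[`, "", 1L)
  resol <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, 0)
  fmt <- toupper(bi$BinaryFormat %||% "IEEE_FLOAT_32")
  datafile <- file.path(dirname(path), ci$DataFile)
  raw_n <- file.size(datafile)
  con <- file(datafile, "rb"); on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    vals <- readBin(con, "double", n = raw_n / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    vals <- readBin(con, "integer", n = raw_n / 2, size = 2, signed = TRUE,
                    endian = "little")
  } else stopf("unsupported BinaryFormat: %s", fmt)
  n_samp <- length(vals) %/% n_ch
  eeg <- matrix(vals[seq_len(n_samp * n_ch)], nrow = n_ch) * resol
  events <- NULL
  mrkfile <- file.path(dirname(path), ci$MarkerFile %||% "")
  if (nzchar(ci$MarkerFile %||% "") && file.exists(mrkfile)) {
    events <- bv_markers_to_events(parse_bv_ini(readLines(mrkfile, warn = FALSE)),
                                   marker_map)
  }
  recording(eeg, fs = fs, channel_labels = labels, events = events)
}

parse_bv_ini <- function(lines) {
  out <- list(); section <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (!is.null(section) && grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

bv_markers_to_events <- function(mrk, marker_map) {
  mk <- mrk[["Marker Infos"]]
  if (is.null(mk)) return(NULL)
  ord <- order(as.integer(sub("^Mk", "", names(mk))))
  rows <- lapply(mk[ord], function(v) strsplit(v, ",")[[1]])
  desc <- unname(vapply(rows, function(r) r[2] %||% "", ""))
  pos <- unname(vapply(rows, function(r) as.integer(r[3]), 0L))
  onset <- offset <- integer(0); label <- character(0)
  open_onset <- NA_integer_; open_label <- NA_character_
  for (i in seq_along(desc)) {
    d <- desc[i]
    role <- marker_role(d, marker_map)
    if (identical(role$role, "onset")) {
      open_onset <- pos[i]; open_label <- role$label
    } else if (identical(role$role, "offset") && !is.na(open_onset)) {
      onset <- c(onset, open_onset); offset <- c(offset, pos[i])
      label <- c(label, open_label)
      open_onset <- NA_integer_
    }
  }
  if (!length(onset)) return(NULL)
  data.frame(onset = onset, offset = offset, label = label)
}

marker_role <- function(desc, marker_map) {
  if (is.null(marker_map)) {
    if (startsWith(desc, "onset:")) {
      return(list(role = "onset", label = sub("^onset:", "", desc)))
    }
    if (identical(desc, "offset")) return(list(role = "offset"))
    return(list(role = "other"))
  }
  if (desc %in% names(marker_map$onsets)) {
    return(list(role = "onset", label = unname(marker_map$onsets[[desc]])))
  }
  if (desc %in% (marker_map$offsets %||% character(0))) {
    return(list(role = "offset"))
  }
  list(role = "other")
}

write_brainvision <- function(rec, stem) {
  stem <- sub("\\.vhdr$", "", stem)
  base <- basename(stem)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$eeg)),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$eeg)), rec$channel_labels)
  )
  writeLines(hdr, paste0(stem, ".vhdr"))
  con <- file(paste0(stem, ".eeg"), "wb")
  writeBin(as.numeric(rec$eeg), con, size = 4, endian = "little")
  close(con)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]")
  i <- 1L
  if (!is.null(rec$events) && nrow(rec$events)) {
    for (r in seq_len(nrow(rec$events))) {
      mk <- c(mk,
        sprintf("Mk%d=Stimulus,onset:%s,%d,1,0", i, rec$events$label[r],
                rec$events$onset[r]),
        sprintf("Mk%d=Stimulus,offset,%d,1,0", i + 1L, rec$events$offset[r]))
      i <- i + 2L
    }
  }
  writeLines(mk, paste0(stem, ".vmrk"))
  invisible(stem)
}
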