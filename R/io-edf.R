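# Minimal EDF (European Data Format) support: continuous 16-bit records,
# one common sampling rate. Amplitudes are quantized to the per-channel
# physical range, so round-trips are exact only to that quantization step.

#' Read a continuous EDF recording
#'
#' Supports plain EDF with a common sampling rate across signals. Annotation
#' channels are not parsed; EDF files carry no trial events here.
#'
#' @param path path to the `.edf` file.
#' @return a [recording()] (EEG only).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header byte count (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L) stopf("EDF signals with mixed rates are not supported")
  fs <- spr[1] / dur
  gain <- (pmax - pmin) / (dmax - dmin)
  eeg <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      eeg[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- pmin[s] + gain[s] * (dig - dmin[s])
    }
  }
  recording(eeg, fs = fs, channel_labels = labels)
}

write_edf <- function(rec, path) {
  path <- if (grepl("\\.edf$", path)) path else paste0(path, ".edf")
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec$eeg); ns <- nrow(rec$eeg)
  n_rec <- ceiling(n / fs)
  pad <- n_rec * fs - n
  x <- if (pad > 0) cbind(rec$eeg, rec$eeg[, rep(n, pad), drop = FALSE]) else rec$eeg
  pmax_ <- apply(abs(x), 1, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_ * 1.0000001)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb"); on.exit(close(con))
  pad_field <- function(v, w) {
    s <- substr(formatC(as.character(v), width = -1), 1, w)
    writeChar(formatC(s, width = -w, flag = "-"), con, eos = NULL)
  }
  pad_field("0", 8); pad_field("synthetic", 80); pad_field("synthetic", 80)
  pad_field("01.01.26", 8); pad_field("00.00.00", 8)
  pad_field(256L * (1L + ns), 8); pad_field("", 44)
  pad_field(n_rec, 8); pad_field("1", 8); pad_field(ns, 4)
  for (v in rec$channel_labels) pad_field(v, 16)
  for (i in seq_len(ns)) pad_field("", 80)
  for (i in seq_len(ns)) pad_field("uV", 8)
  for (i in seq_len(ns)) pad_field(sprintf("%.6g", -pmax_[i]), 8)
  for (i in seq_len(ns)) pad_field(sprintf("%.6g", pmax_[i]), 8)
  for (i in seq_len(ns)) pad_field(dmin, 8)
  for (i in seq_len(ns)) pad_field(dmax, 8)
  for (i in seq_len(ns)) pad_field("", 80)
  for (i in seq_len(ns)) pad_field(fs, 8)
  for (i in seq_len(ns)) pad_field("", 32)
  scale <- (dmax - dmin) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- as.integer(round((x[s, idx] + pmax_[s]) * scale[s]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
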