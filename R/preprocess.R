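# Signal-conditioning chain: detrend -> high-pass -> (projection hook) ->
# low-pass -> downsample -> differentiate -> lag-embed -> segment ->
# standardize. All filters are zero-phase (forward-backward Butterworth),
# so the squared magnitude response applies and no group delay is
# introduced.

filtfilt_pad <- function(filt, x) {
  # odd-reflection padding keeps the forward-backward pass from ringing at
  # the edges on short signals
  n <- length(x)
  p <- min(n - 1L, 3L * (length(filt$a) + length(filt$b)))
  if (p < 1L) return(signal::filtfilt(filt, x))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(p + 1):(p + n)]
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2          # centered time axis
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

filter_matrix <- function(x, fs, band, order, detrend = TRUE) {
  nyq <- fs / 2
  if (band[2] >= nyq) stopf("band edge %g Hz is at or above Nyquist (%g Hz)", band[2], nyq)
  if (ncol(x) <= 3 * order) stopf("signal too short for an order-%d filter", order)
  lp <- signal::butter(order, band[2] / nyq, type = "low")
  hp <- if (band[1] > 0) signal::butter(order, band[1] / nyq, type = "high") else NULL
  out <- x
  for (i in seq_len(nrow(x))) {
    v <- if (detrend) detrend_linear(x[i, ]) else x[i, ]
    if (!is.null(hp)) v <- filtfilt_pad(hp, v)
    out[i, ] <- filtfilt_pad(lp, v)
  }
  out
}

#' Band-limit the EEG of a recording
#'
#' Removes the linear trend, then applies a zero-phase high-pass at
#' `band[1]` (skipped when 0) and a zero-phase low-pass at `band[2]`, each a
#' Butterworth of the given order run forward and backward. Kinematics are
#' left untouched; see [lowpass_kinematics()].
#'
#' @param rec a [recording()].
#' @param band length-2 numeric band edges in Hz, low < high < Nyquist.
#' @param order Butterworth order.
#' @return the recording with filtered EEG.
#' @export
bandlimit_eeg <- function(rec, band = c(0.3, 1), order = 4L) {
  stopifnot(inherits(rec, "grasp_recording"))
  if (band[1] < 0 || band[1] >= band[2]) stopf("band edges must satisfy 0 <= low < high")
  rec$eeg <- filter_matrix(rec$eeg, rec$fs, band, order)
  rec
}

#' Low-pass filter the kinematics of a recording
#'
#' Zero-phase Butterworth low-pass on the joint-angle traces, and the
#' signal-to-error ratio (SER, dB) of each joint quantifying the distortion
#' the filter introduced.
#'
#' @param rec a [recording()] with kinematics.
#' @param cutoff low-pass edge in Hz.
#' @param order Butterworth order.
#' @return the recording with filtered kinematics and an `ser_db` attribute
#'   (named per joint).
#' @export
lowpass_kinematics <- function(rec, cutoff = 1, order = 4L) {
  stopifnot(inherits(rec, "grasp_recording"))
  if (is.null(rec$kin)) stopf("recording has no kinematics")
  raw <- rec$kin
  rec$kin <- filter_matrix(rec$kin, rec$fs, c(0, cutoff), order, detrend = FALSE)
  ser <- vapply(seq_len(nrow(raw)),
                function(j) compute_ser(raw[j, ], rec$kin[j, ]), 0)
  names(ser) <- rec$joint_labels
  attr(rec, "ser_db") <- ser
  rec
}

#' Apply a spatial projection to the EEG
#'
#' Hook for artifact removal in sensor space: the EEG is left-multiplied by
#' a square channels x channels matrix (e.g. identity minus an ocular
#' subspace projector). Component identification itself is outside the
#' pipeline; only the resulting projection is applied.
#'
#' @param rec a [recording()].
#' @param projection square numeric matrix, dimension = channel count.
#' @return the recording with projected EEG; labels unchanged.
#' @export
apply_spatial_projection <- function(rec, projection) {
  stopifnot(inherits(rec, "grasp_recording"))
  projection <- as.matrix(projection)
  nc <- nrow(rec$eeg)
  if (nrow(projection) != nc || ncol(projection) != nc) {
    stopf("projection must be %d x %d (got %d x %d)", nc, nc,
          nrow(projection), ncol(projection))
  }
  rec$eeg <- projection %*% rec$eeg
  rownames(rec$eeg) <- rec$channel_labels
  rec
}

#' Drop named channels from a recording
#'
#' @param rec a [recording()].
#' @param labels channel labels to drop (must all exist); the order of the
#'   remaining channels is preserved. An empty set is the identity.
#' @return the recording without the named channels.
#' @export
exclude_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "grasp_recording"))
  labels <- as.character(labels)
  if (!length(labels)) return(rec)
  unknown <- setdiff(labels, rec$channel_labels)
  if (length(unknown)) stopf("unknown channel label(s): %s", paste(unknown, collapse = ", "))
  keep <- !(rec$channel_labels %in% labels)
  rec$eeg <- rec$eeg[keep, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[keep]
  rec
}

#' Downsample and differentiate a recording
#'
#' Decimates EEG and kinematics by the integer factor `fs / target_fs`
#' (band-limiting must already have removed content above the new Nyquist),
#' then takes the first difference scaled by `target_fs`, giving physical
#' rates (microvolts/s, deg/s). Output length is preserved by repeating the
#' first difference at the start. Event indices are mapped to the new rate.
#'
#' @param rec a [recording()].
#' @param target_fs target sampling rate; must divide `rec$fs`.
#' @return the differentiated recording at `target_fs`.
#' @export
resample_and_differentiate <- function(rec, target_fs = 100) {
  stopifnot(inherits(rec, "grasp_recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stopf("target_fs (%g) must divide the sampling rate (%g)", target_fs, rec$fs)
  }
  factor <- as.integer(round(factor))
  dec <- function(m) m[, seq(1L, ncol(m), by = factor), drop = FALSE]
  diff_rows <- function(m) {
    d <- (m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]) * target_fs
    cbind(d[, 1L, drop = FALSE], d)
  }
  rec$eeg <- diff_rows(dec(rec$eeg))
  if (!is.null(rec$kin)) rec$kin <- diff_rows(dec(rec$kin))
  if (!is.null(rec$events)) {
    rec$events$onset <- (rec$events$onset - 1L) %/% factor + 1L
    rec$events$offset <- (rec$events$offset - 1L) %/% factor + 1L
  }
  rec$fs <- target_fs
  rec
}

#' Signal-to-error ratio in dB
#'
#' `10 log10(Var(raw) / MSE(raw, filtered))`; the standard check that a
#' smoothing filter did not distort the signal it was meant to clean.
#'
#' @param raw,filtered equal-length numeric vectors.
#' @return SER in dB (`Inf` when the MSE is zero).
#' @export
compute_ser <- function(raw, filtered) {
  if (length(raw) != length(filtered)) stopf("raw and filtered must have equal length")
  v <- var(raw)
  if (!is.finite(v) || v <= 0) stopf("raw signal has zero variance")
  mse <- mean((raw - filtered)^2)
  if (mse == 0) return(Inf)
  10 * log10(v / mse)
}

#' Lag-embed the EEG of a recording
#'
#' Stacks L + 1 time-shifted copies of each channel so that one time point
#' carries a 0..L*step history: entry `[t, n, k+1]` equals channel n at time
#' `t - k*step`. Samples with `t <= L*step` precede the available history
#' and are flagged invalid (`valid_from`); segmentation never touches them
#' because the pre-onset margin exceeds the maximum lag.
#'
#' @param rec a [recording()] already at the decoding rate.
#' @param L maximum lag in samples (L + 1 lag copies).
#' @param step lag step in samples.
#' @return an object of class `lag_tensor`: list with `data`
#'   (time x channels x lags array), `L`, `step`, `lag_ms`, `valid_from`,
#'   `fs`, `channel_labels`.
#' @export
lag_embed <- function(rec, L = 10L, step = 1L) {
  stopifnot(inherits(rec, "grasp_recording"))
  if (L < 0L) stopf("L must be non-negative")
  if (step < 1L) stopf("step must be >= 1")
  n <- ncol(rec$eeg); nc <- nrow(rec$eeg)
  if (L * step >= n) stopf("lag span (%d samples) exceeds recording length", L * step)
  x <- t(rec$eeg)                                  # time x channels
  data <- array(0, dim = c(n, nc, L + 1L),
                dimnames = list(NULL, rec$channel_labels,
                                paste0("lag", 0:L * step)))
  for (k in 0:L) {
    s <- k * step
    data[, , k + 1L] <- rbind(x[rep(1L, s), , drop = FALSE],
                              x[seq_len(n - s), , drop = FALSE])
  }
  structure(list(data = data, L = as.integer(L), step = as.integer(step),
                 lag_ms = (0:L) * step / rec$fs * 1000,
                 valid_from = as.integer(L * step + 1L), fs = rec$fs,
                 channel_labels = rec$channel_labels),
            class = "lag_tensor")
}

#' Segment a lag tensor and kinematics into trials
#'
#' One trial per event, spanning `pre_ms` before movement onset to `post_ms`
#' after movement offset (inclusive). Trials whose window (including lag
#' history) leaves the recording are rejected with a warning, never
#' silently.
#'
#' @param lagged a [lag_embed()] result.
#' @param kin_rec the matching [recording()] holding joint velocities at the
#'   same rate.
#' @param events event data.frame (`onset`, `offset`, `label`) in samples at
#'   the decoding rate.
#' @param pre_ms,post_ms segmentation margins in ms.
#' @return an object of class `trial_set`: per-trial lagged EEG
#'   (time x channels x lags), joint velocities (time x 15), labels.
#' @export
segment_trials <- function(lagged, kin_rec, events, pre_ms = 400, post_ms = 100) {
  stopifnot(inherits(lagged, "lag_tensor"))
  fs <- lagged$fs
  pre <- as.integer(round(pre_ms / 1000 * fs))
  post <- as.integer(round(post_ms / 1000 * fs))
  n <- dim(lagged$data)[1]
  kin <- if (!is.null(kin_rec)) kin_rec$kin else NULL
  trials <- list(); dropped <- 0L
  for (i in seq_len(nrow(events))) {
    start <- events$onset[i] - pre
    end <- events$offset[i] + post
    if (start < lagged$valid_from || end > n) {
      dropped <- dropped + 1L
      next
    }
    idx <- start:end
    trials[[length(trials) + 1L]] <- list(
      eeg = lagged$data[idx, , , drop = FALSE],
      vel = if (!is.null(kin)) t(kin[, idx, drop = FALSE]) else NULL,
      pc = NULL,
      label = events$label[i],
      onset_in_trial = pre + 1L,
      n = length(idx)
    )
  }
  if (dropped > 0L) {
    warnf("%d trial(s) rejected: window (plus lag history) outside the recording", dropped)
  }
  structure(list(trials = trials, channel_labels = lagged$channel_labels,
                 joint_labels = if (!is.null(kin_rec)) kin_rec$joint_labels else NULL,
                 L = lagged$L, step = lagged$step, fs = fs,
                 pre_ms = pre_ms, post_ms = post_ms,
                 standardized = FALSE, stats = NULL),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  lab <- table(vapply(x$trials, `[[`, "", "label"))
  cat(sprintf("<trial_set> %d trial(s), %d channel(s) x %d lag(s) @ %g Hz\n",
              length(x$trials), length(x$channel_labels), x$L + 1L, x$fs))
  if (length(lab)) {
    cat("  labels:", paste(sprintf("%s:%d", names(lab), as.integer(lab)),
                           collapse = ", "), "\n")
  }
  if (x$standardized) cat("  features standardized\n")
  invisible(x)
}

trial_labels <- function(trials) vapply(trials$trials, `[[`, "", "label")

# mean/sd per (channel, lag) feature over all time points of all trials
feature_stats <- function(trials) {
  dims <- dim(trials$trials[[1]]$eeg)[2:3]
  s <- matrix(0, dims[1], dims[2]); s2 <- matrix(0, dims[1], dims[2]); n <- 0
  for (tr in trials$trials) {
    s <- s + colSums(tr$eeg)
    s2 <- s2 + apply(tr$eeg^2, c(2, 3), sum)
    n <- n + tr$n
  }
  mean_ <- s / n
  var_ <- (s2 - n * mean_^2) / (n - 1)
  list(mean = mean_, sd = sqrt(pmax(var_, 0)), n = n)
}

#' Standardize trial features
#'
#' Centers and scales every (channel, lag) feature to zero mean and unit
#' standard deviation over all time points of all trials, storing the
#' statistics for reuse on held-out data (fold-safe cross-validation passes
#' the training-fold statistics through `stats`). Zero-variance features are
#' set to zero with a warning.
#'
#' @param trials a [segment_trials()] result.
#' @param stats optional statistics (`mean`, `sd` matrices) to apply instead
#'   of computing them from `trials`.
#' @return the standardized `trial_set`, with the statistics in `$stats`.
#' @export
standardize_trials <- function(trials, stats = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  if (!length(trials$trials)) stopf("empty trial set")
  if (is.null(stats)) stats <- feature_stats(trials)
  zero <- stats$sd <= 0
  if (any(zero)) {
    warnf("%d zero-variance feature(s) left at 0 after centering", sum(zero))
  }
  sd_safe <- ifelse(zero, 1, stats$sd)
  for (i in seq_along(trials$trials)) {
    e <- trials$trials[[i]]$eeg
    e <- sweep(e, c(2, 3), stats$mean, "-")
    e <- sweep(e, c(2, 3), sd_safe, "/")
    if (any(zero)) {
      for (d in which(zero)) {
        ij <- arrayInd(d, dim(zero))
        e[, ij[1], ij[2]] <- 0
      }
    }
    trials$trials[[i]]$eeg <- e
  }
  trials$standardized <- TRUE
  trials$stats <- stats
  trials
}

#' Run the full preprocessing chain on a recording
#'
#' Kinematics: low-pass (with SER check), downsample, differentiate to
#' angular velocities. EEG: detrend + high-pass, optional spatial
#' projection, low-pass, channel exclusion, downsample, differentiate, lag
#' embed. Finally segments both into trials. Standardization is left to the
#' decoding stage so that fold-safe statistics remain possible.
#'
#' @param rec a [recording()] with events (kinematics optional).
#' @param config a [pipeline_config()].
#' @param projection optional spatial projection matrix (applied between the
#'   high-pass and low-pass, full montage dimension).
#' @param extra_exclude additional channel labels to drop, e.g. the frontal
#'   set of the ocular-artifact control.
#' @return an object of class `preprocessed_recording`: `trials` (a
#'   `trial_set`), `lagged` (continuous lag tensor), `events` (at the
#'   decoding rate), `ser_db`, `config`.
#' @export
preprocess_recording <- function(rec, config = pipeline_config(),
                                 projection = NULL, extra_exclude = NULL) {
  stopifnot(inherits(rec, "grasp_recording"))
  if (is.null(rec$events)) stopf("recording has no events to segment")
  cont <- preprocess_continuous(rec, config, projection, extra_exclude)
  embed_and_segment(cont, config)
}

# stage 1: filtering, projection, exclusion, downsampling, differentiation
# of the continuous streams (no lag embedding yet)
preprocess_continuous <- function(rec, config, projection = NULL,
                                  extra_exclude = NULL) {
  ser <- NULL
  kin_rec <- NULL
  if (!is.null(rec$kin)) {
    filtered <- lowpass_kinematics(rec, cutoff = config$filter_band[2],
                                   order = config$filter_order)
    ser <- attr(filtered, "ser_db")
    # carry only the kinematics through the resampler (EEG handled below)
    kin_only <- recording(matrix(0, 1, ncol(rec$eeg)), fs = rec$fs,
                          channel_labels = "placeholder", kin = filtered$kin,
                          joint_labels = rec$joint_labels)
    kin_rec <- resample_and_differentiate(kin_only, config$target_fs)
  }
  eeg_rec <- rec
  eeg_rec$kin <- NULL; eeg_rec$joint_labels <- NULL
  eeg_rec <- bandlimit_eeg(eeg_rec, band = config$filter_band,
                           order = config$filter_order)
  if (!is.null(projection)) eeg_rec <- apply_spatial_projection(eeg_rec, projection)
  drop <- intersect(c(config$excluded_channels, extra_exclude), eeg_rec$channel_labels)
  eeg_rec <- exclude_channels(eeg_rec, drop)
  eeg_rec <- resample_and_differentiate(eeg_rec, config$target_fs)
  list(eeg_rec = eeg_rec, kin_rec = kin_rec, ser_db = ser)
}

# stage 2: lag embedding and trial segmentation
embed_and_segment <- function(cont, config) {
  lagged <- lag_embed(cont$eeg_rec, L = config$max_lag, step = config$lag_step)
  trials <- segment_trials(lagged, cont$kin_rec, cont$eeg_rec$events,
                           pre_ms = config$pre_ms, post_ms = config$post_ms)
  structure(list(trials = trials, lagged = lagged, events = cont$eeg_rec$events,
                 ser_db = cont$ser_db, config = config,
                 channel_labels = cont$eeg_rec$channel_labels),
            class = "preprocessed_recording")
}
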