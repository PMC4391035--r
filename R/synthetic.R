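# Synthetic EEG/kinematics generator. It emulates the statistical structure
# the decoder assumes: three latent velocity synergies with biphasic
# (open/close) per-object profiles, joint velocities spanned by an
# orthonormal 15 x 3 loading matrix, and EEG whose informative channels
# carry the position-like running integral of each synergy at
# channel-specific 40-100 ms leads, buried in white + 1/f noise. Because the
# preprocessing chain differentiates EEG, the first difference of the clean
# EEG is an exactly lagged linear image of the velocity synergies, which is
# the premise of the Wiener decoder.

default_synergy_loadings <- function() {
  w <- matrix(0, 15, 3, dimnames = list(default_joint_labels(), paste0("PC", 1:3)))
  # grasp aperture: finger MCP/PIP flexion, PIP-dominant
  w[c("index_MCP", "middle_MCP", "ring_MCP", "little_MCP"), 1] <- 0.30
  w[c("index_PIP", "middle_PIP", "ring_PIP", "little_PIP"), 1] <- 0.40
  # hand spread: abduction joints
  w[c("ABD_thumb_index", "ABD_index_middle", "ABD_middle_ring", "ABD_ring_little"), 2] <-
    c(0.55, 0.55, 0.45, 0.44)
  # independent thumb motion
  w[c("thumb_CMC", "thumb_MCP", "thumb_IP"), 3] <- c(0.55, 0.62, 0.56)
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

default_object_profiles <- function() {
  # peak opening velocity (synergy units ~ deg/s) and bump timing/widths as
  # fractions of movement duration, one entry per synergy. Closing
  # amplitudes are set inside the generator so each trial's net excursion
  # is zero (the hand returns to rest within a trial). Amplitude ratios put
  # roughly 50/30/10 percent of the pooled velocity variance on the three
  # synergies. Object identity is carried by amplitudes, by object-specific
  # timing and by the sign of the spread/thumb components (the hand spreads
  # for a CD but narrows for a card or penny). Timings and widths are fixed
  # so that (i) the amplitude-weighted across-object mean of each synergy
  # profile nearly cancels -- trials are mutually out of phase, which is
  # what makes trial-scrambled decoding a valid chance level -- and (ii)
  # the three synergies are mutually uncorrelated over the pooled session,
  # so the PCA of joint velocities recovers them as separate components.
  list(
    can = list(a_open = c(358, 140, 91),
      t_open = c(0.498, 0.352, 0.277), t_close = c(0.578, 0.701, 0.939),
      w_open = c(0.071, 0.080, 0.050), w_close = c(0.180, 0.180, 0.178)),
    card = list(a_open = c(215, -92, 51),
      t_open = c(0.109, 0.448, 0.523), t_close = c(0.188, 0.703, 0.939),
      w_open = c(0.180, 0.179, 0.180), w_close = c(0.089, 0.180, 0.172)),
    cd = list(a_open = c(286, 122, -63),
      t_open = c(0.800, 0.131, 0.349), t_close = c(0.925, 0.460, 0.940),
      w_open = c(0.050, 0.050, 0.180), w_close = c(0.180, 0.115, 0.172)),
    penny = list(a_open = c(131, -53, 36),
      t_open = c(0.468, 0.249, 0.227), t_close = c(0.548, 0.938, 0.307),
      w_open = c(0.052, 0.180, 0.178), w_close = c(0.180, 0.155, 0.125)),
    screwdriver = list(a_open = c(322, 122, -89),
      t_open = c(0.272, 0.512, 0.736), t_close = c(0.436, 0.929, 0.816),
      w_open = c(0.071, 0.091, 0.050), w_close = c(0.050, 0.152, 0.180))
  )
}

default_coupling <- function(informative_channels) {
  n <- length(informative_channels)
  lags <- rep(c(40, 50, 60, 70, 80, 90, 100, 45, 55, 65, 85, 95),
              length.out = n)
  base <- matrix(c(
     0.95,  0.25, -0.15,
    -0.55,  0.85,  0.30,
     0.35, -0.65,  0.80,
     0.75,  0.45,  0.55,
    -0.85, -0.20,  0.45,
     0.25,  0.95, -0.35,
     0.60, -0.40, -0.75,
    -0.30,  0.70,  0.65,
     0.85, -0.55,  0.25,
    -0.45, -0.80, -0.50,
     0.50,  0.35,  0.90,
    -0.70,  0.60, -0.40
  ), ncol = 3, byrow = TRUE)
  gains <- 0.12 * base[rep(seq_len(nrow(base)), length.out = n), , drop = FALSE]
  list(channels = informative_channels, lag_ms = lags[seq_len(n)], gains = gains)
}

#' Specification of a synthetic recording
#'
#' Collects every knob of the generator. The defaults are the study
#' conditions: 64 channels at 1000 Hz, 50 trials for each of 5 objects,
#' movement time 1.9 +/- 0.3 s with 1-2 s inter-trial rests, 3 latent
#' synergies, EEG coupling on 12 contralateral sensorimotor/parietal
#' channels at 40-100 ms leads, and in-band (0.1-1 Hz) SNR 10.
#'
#' @param n_channels number of EEG channels; 64 selects the default montage,
#'   otherwise `montage` must be supplied.
#' @param montage channel labels (length `n_channels`).
#' @param fs sampling rate in Hz.
#' @param trials_per_object trials for each object (>= 1).
#' @param objects object labels.
#' @param move_dur_mean,move_dur_sd movement duration distribution, seconds.
#' @param rest_range inter-trial rest interval, seconds.
#' @param pad_s quiet padding at the recording edges, seconds.
#' @param w_true 15 x 3 orthonormal synergy loading matrix.
#' @param object_profiles per-object synergy amplitude/timing parameters,
#'   see `default_object_profiles()`.
#' @param amp_jitter_sd per-trial multiplicative amplitude jitter (sd).
#' @param time_jitter_sd per-trial timing jitter of each synergy's bumps,
#'   as an sd in movement-duration fractions (self-paced variability).
#' @param informative_channels labels of EEG channels carrying kinematic
#'   signal; must be part of the montage.
#' @param coupling list with `channels`, `lag_ms` (within 0-100 ms) and
#'   `gains` (channels x 3): the EEG forward model.
#' @param snr in-band signal-to-noise variance ratio on informative
#'   channels; `Inf` for noise-free EEG.
#' @param white_mix fraction of noise variance that is white (the rest is
#'   1/f-shaped).
#' @param pink_exponent spectral exponent of the shaped noise.
#' @param kin_noise_sd kinematic sensor noise on joint velocities (deg/s).
#' @param artifact optional ocular artifact: list with `channels`, `weights`
#'   and `amplitude` (microvolts, sd of a low-frequency random walk). Off by
#'   default.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 64L,
                           montage = if (n_channels == 64L) default_montage() else NULL,
                           fs = 1000,
                           trials_per_object = 50L,
                           objects = object_labels(),
                           move_dur_mean = 1.9,
                           move_dur_sd = 0.3,
                           rest_range = c(1, 2),
                           pad_s = 2.5,
                           w_true = default_synergy_loadings(),
                           object_profiles = default_object_profiles(),
                           amp_jitter_sd = 0.10,
                           time_jitter_sd = 0.05,
                           informative_channels = c("C1", "C3", "C5", "FC1", "FC3",
                                                    "CP1", "CP3", "CP5", "P1", "P3",
                                                    "Cz", "Pz"),
                           coupling = default_coupling(informative_channels),
                           snr = 10,
                           white_mix = 0.3,
                           pink_exponent = 1,
                           kin_noise_sd = 1,
                           artifact = NULL) {
  if (is.null(montage) || length(montage) != n_channels) {
    stopf("montage must supply %d channel labels", n_channels)
  }
  if (trials_per_object < 1L) stopf("degenerate spec: trials_per_object must be >= 1")
  if (!length(objects)) stopf("degenerate spec: no objects")
  if (!length(coupling$channels)) stopf("degenerate spec: empty coupling")
  if (!all(coupling$channels %in% montage)) {
    stopf("coupling channels must be part of the montage")
  }
  if (!setequal(coupling$channels, informative_channels) ||
      !all(coupling$channels %in% informative_channels)) {
    stopf("coupling must be restricted to the informative channel set")
  }
  if (any(coupling$lag_ms < 0 | coupling$lag_ms > 100)) {
    stopf("coupling lags must lie within 0-100 ms")
  }
  if (!all(names(object_profiles) == objects)) {
    stopf("object_profiles must be named exactly by the objects")
  }
  ortho <- crossprod(w_true)
  if (max(abs(ortho - diag(ncol(w_true)))) > 1e-8) {
    stopf("w_true columns must be orthonormal")
  }
  structure(
    list(n_channels = as.integer(n_channels), montage = montage, fs = fs,
         trials_per_object = as.integer(trials_per_object), objects = objects,
         move_dur_mean = move_dur_mean, move_dur_sd = move_dur_sd,
         rest_range = rest_range, pad_s = pad_s, w_true = w_true,
         object_profiles = object_profiles, amp_jitter_sd = amp_jitter_sd,
         time_jitter_sd = time_jitter_sd,
         informative_channels = informative_channels, coupling = coupling,
         snr = snr, white_mix = white_mix, pink_exponent = pink_exponent,
         kin_noise_sd = kin_noise_sd, artifact = artifact),
    class = "synthetic_spec"
  )
}

# 1/f^a noise by spectral shaping of white noise, returned with unit
# variance. The transform length is rounded up to a highly composite value
# (mixed-radix FFTs degrade badly on near-prime lengths) and truncated.
shaped_noise <- function(n, exponent) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- fft(rnorm(m))
  f <- seq(0, floor(m / 2), by = 1) / m          # cycles/sample, DC..Nyquist
  amp <- c(0, pmax(f[-1], 1 / m)^(-exponent / 2))
  full <- c(amp, rev(amp[2:(m - length(amp) + 1)]))
  y <- Re(fft(x * full, inverse = TRUE))[seq_len(n)] / m
  y / sd(y)
}

simulate_core <- function(spec, seed) {
  with_seed(seed, {
    fs <- spec$fs
    n_trials <- spec$trials_per_object * length(spec$objects)
    labels <- sample(rep(spec$objects, each = spec$trials_per_object))
    durs <- rnorm(n_trials, spec$move_dur_mean, spec$move_dur_sd)
    durs <- pmin(pmax(durs, spec$move_dur_mean - 3 * spec$move_dur_sd),
                 spec$move_dur_mean + 3 * spec$move_dur_sd)
    durs <- pmax(durs, 0.5)
    rests <- runif(n_trials, spec$rest_range[1], spec$rest_range[2])
    onset_s <- spec$pad_s + cumsum(c(0, head(durs + rests, -1)))
    offset_s <- onset_s + durs
    # session length padded up to a highly composite sample count (so that
    # full-length FFTs -- noise shaping, phase-scrambled surrogates -- stay
    # fast) while remaining divisible by the decimation factor to 100 Hz
    n_raw <- ceiling((tail(offset_s, 1) + spec$pad_s) * fs)
    dec <- max(1L, as.integer(round(fs / 100)))
    n <- stats::nextn(ceiling(n_raw / dec), c(2, 3, 5)) * dec
    onset <- pmax(1L, as.integer(round(onset_s * fs)) + 1L)
    offset <- as.integer(round(offset_s * fs)) + 1L

    # latent synergy velocity trajectories, biphasic with zero net excursion
    pc <- matrix(0, 3, n)
    for (tr in seq_len(n_trials)) {
      p <- spec$object_profiles[[labels[tr]]]
      idx <- onset[tr]:offset[tr]
      t_rel <- (idx - onset[tr]) / (offset[tr] - onset[tr])
      jit <- 1 + spec$amp_jitter_sd * rnorm(3)
      tj <- spec$time_jitter_sd * rnorm(3)
      for (c_i in 1:3) {
        t_o <- min(max(p$t_open[c_i] + tj[c_i], 0.05), 0.95)
        t_c <- min(max(p$t_close[c_i] + tj[c_i], 0.05), 0.95)
        open_b <- exp(-((t_rel - t_o) / p$w_open[c_i])^2 / 2)
        close_b <- exp(-((t_rel - t_c) / p$w_close[c_i])^2 / 2)
        a <- p$a_open[c_i] * jit[c_i]
        pc[c_i, idx] <- a * open_b -
          a * (p$w_open[c_i] / p$w_close[c_i]) * close_b
      }
    }

    vel <- spec$w_true %*% pc + spec$kin_noise_sd * matrix(rnorm(15 * n), 15)
    angles <- t(apply(vel, 1, cumsum)) / fs + seq(5, 40, length.out = 15)

    # clean EEG: position-like integrals of the synergies at per-channel leads
    q <- t(apply(pc, 1, cumsum)) / fs
    sig <- matrix(0, spec$n_channels, n, dimnames = list(spec$montage, NULL))
    lag_smp <- as.integer(round(spec$coupling$lag_ms / 1000 * fs))
    for (i in seq_along(spec$coupling$channels)) {
      ch <- match(spec$coupling$channels[i], spec$montage)
      k <- lag_smp[i]
      shifted <- q[, c((k + 1):n, rep(n, k)), drop = FALSE]
      sig[ch, ] <- as.numeric(spec$coupling$gains[i, , drop = FALSE] %*% shifted)
    }

    noise <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      noise[ch, ] <- sqrt(spec$white_mix) * rnorm(n) +
        sqrt(1 - spec$white_mix) * shaped_noise(n, spec$pink_exponent)
    }

    info_idx <- match(spec$informative_channels, spec$montage)
    sig_var <- mean(vapply(info_idx, function(ch) band_variance(sig[ch, ], fs), 0))
    noise_var <- mean(vapply(info_idx, function(ch) band_variance(noise[ch, ], fs), 0))

    artifact_pattern <- NULL
    artifact_course <- NULL
    if (!is.null(spec$artifact)) {
      artifact_pattern <- numeric(spec$n_channels)
      names(artifact_pattern) <- spec$montage
      artifact_pattern[spec$artifact$channels] <- spec$artifact$weights
      rw <- cumsum(rnorm(n))
      artifact_course <- spec$artifact$amplitude * rw / sd(rw)
    }

    list(sig = sig, noise = noise, sig_var = sig_var, noise_var = noise_var,
         pc = pc, vel = vel, angles = angles, labels = labels,
         onset = onset, offset = offset, n = n,
         artifact_pattern = artifact_pattern, artifact_course = artifact_course)
  })
}

assemble_recording <- function(spec, core, snr, seed) {
  lambda <- if (is.infinite(snr)) 0 else sqrt(core$sig_var / (snr * core$noise_var))
  eeg <- core$sig + lambda * core$noise
  if (!is.null(core$artifact_pattern)) {
    eeg <- eeg + outer(core$artifact_pattern, core$artifact_course)
  }
  events <- data.frame(onset = core$onset, offset = core$offset,
                       label = core$labels)
  rec <- recording(eeg, fs = spec$fs, channel_labels = spec$montage,
                   kin = core$angles, joint_labels = default_joint_labels(),
                   events = events)
  truth <- structure(
    list(pc = core$pc, w_true = spec$w_true, coupling = spec$coupling,
         labels = core$labels, informative_channels = spec$informative_channels,
         noise_lambda = lambda, snr = snr, seed = seed,
         artifact_pattern = core$artifact_pattern),
    class = "ground_truth"
  )
  list(recording = rec, truth = truth)
}

#' Simulate a synthetic EEG/kinematics recording
#'
#' Draws one full session from a [synthetic_spec()]: trial timeline, latent
#' synergy trajectories, joint kinematics, coupled EEG, noise and events.
#' Identical `seed` gives byte-identical output; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return list with elements `recording` (a [recording()]) and `truth`
#'   (ground truth: latent synergy trajectories `pc`, loading matrix
#'   `w_true`, coupling, trial labels, noise scale, artifact pattern).
#' @export
simulate_recording <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  core <- simulate_core(spec, seed)
  assemble_recording(spec, core, spec$snr, seed)
}

#' Generate recordings that differ only in noise scale
#'
#' Simulates the session once and returns one recording per requested SNR,
#' sharing signal, kinematics and events; only the noise amplitude changes.
#'
#' @param spec a [synthetic_spec()].
#' @param snr_values positive (or infinite) in-band SNR values.
#' @param seed integer seed.
#' @return list of `list(recording, truth)` pairs, one per SNR.
#' @export
snr_sweep <- function(spec, snr_values, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(snr_values)) stopf("snr_values must be non-empty")
  if (any(snr_values <= 0)) stopf("snr_values must be positive or infinite")
  core <- simulate_core(spec, seed)
  lapply(snr_values, function(s) assemble_recording(spec, core, s, seed))
}
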