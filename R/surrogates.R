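# Empirical chance levels. Phase scrambling randomizes Fourier phases per
# channel while preserving each magnitude spectrum (hence the
# autocovariance), destroying the phase locking between EEG and kinematics
# that time-domain decoding relies on. Fold scrambling breaks the
# trial-level pairing between EEG and kinematics instead.

phase_scramble_vector <- function(x) {
  n <- length(x)
  xf <- fft(x)
  half <- seq(2L, ceiling((n + 1) / 2))      # non-DC, non-Nyquist positive bins
  if (n %% 2 == 0) half <- half[-length(half)]
  phases <- runif(length(half), 0, 2 * pi)
  xf[half] <- Mod(xf[half]) * exp(1i * phases)
  xf[n + 2L - half] <- Conj(xf[half])
  Re(fft(xf, inverse = TRUE)) / n
}

#' Phase-scramble the EEG of a recording
#'
#' Per channel: discrete Fourier transform, replacement of all non-DC,
#' non-Nyquist phases by independent uniform draws with conjugate symmetry
#' enforced, inverse transform. The magnitude spectrum (and autocovariance)
#' of every channel is preserved exactly; phases are independent across
#' channels. Kinematics and events are untouched.
#'
#' @param rec a [recording()].
#' @param seed integer seed.
#' @return the recording with surrogate EEG.
#' @export
phase_scramble <- function(rec, seed = 1L) {
  stopifnot(inherits(rec, "grasp_recording"))
  if (ncol(rec$eeg) == 0L) stopf("empty signal")
  with_seed(seed, {
    for (i in seq_len(nrow(rec$eeg))) {
      rec$eeg[i, ] <- phase_scramble_vector(rec$eeg[i, ])
    }
  })
  rec
}

#' Scramble the EEG/kinematics pairing across trials
#'
#' Permutes the lagged EEG tensors across trials (derangement enforced: no
#' trial keeps its own EEG) while kinematics stay in place, so EEG for one
#' object's kinematics comes from some other trial. Length mismatches are
#' reconciled by truncating both streams of a pair to the shorter one, and
#' the truncation is logged.
#'
#' @param trials a `trial_set` with at least 2 trials.
#' @param seed integer seed.
#' @return the scrambled `trial_set`.
#' @export
fold_scramble <- function(trials, seed = 1L) {
  stopifnot(inherits(trials, "trial_set"))
  n <- length(trials$trials)
  if (n < 2L) stopf("fold scrambling needs at least 2 trials")
  perm <- with_seed(seed, {
    repeat {
      p <- sample(n)
      if (all(p != seq_len(n))) break
    }
    p
  })
  out <- trials
  truncated <- 0L
  for (i in seq_len(n)) {
    donor <- trials$trials[[perm[i]]]
    keep <- trials$trials[[i]]
    len <- min(donor$n, keep$n)
    if (donor$n != keep$n) truncated <- truncated + 1L
    keep$eeg <- donor$eeg[seq_len(len), , , drop = FALSE]
    keep$vel <- keep$vel[seq_len(len), , drop = FALSE]
    if (!is.null(keep$pc)) keep$pc <- keep$pc[seq_len(len), , drop = FALSE]
    keep$n <- len
    out$trials[[i]] <- keep
  }
  if (truncated > 0L) {
    message(sprintf("fold_scramble: %d pair(s) truncated to the shorter trial", truncated))
  }
  attr(out, "permutation") <- perm
  out
}

#' Empirical chance levels for the decoder
#'
#' Repeats the full cross-validated decoding on surrogate data
#' (`method = "phase"`: phase-scrambled continuous EEG, re-preprocessed and
#' re-embedded; `method = "fold"`: trial-pairing scrambled after
#' segmentation) and aggregates the per-repetition median correlations.
#' Repetition seeds are derived from `seed` and recorded, so a rerun
#' reproduces the result exactly.
#'
#' @param rec the raw [recording()] (with events and kinematics).
#' @param config a [pipeline_config()].
#' @param method `"phase"` or `"fold"`.
#' @param repetitions number of surrogate repetitions.
#' @param seed integer seed.
#' @return an object of class `null_result`: `method`, `median_r`
#'   (repetitions x outputs), `mean`, `sem`, `seeds`.
#' @export
chance_level_suite <- function(rec, config = pipeline_config(),
                               method = c("phase", "fold"),
                               repetitions = config$surrogate_reps,
                               seed = config$seed) {
  stopifnot(inherits(rec, "grasp_recording"))
  method <- match.arg(method)
  if (repetitions < 1L) stopf("repetitions must be >= 1")
  seeds <- seed + seq_len(repetitions) * 1000L
  prep <- if (method == "fold") preprocess_recording(rec, config) else NULL
  cont <- if (method == "phase") {
    preprocess_continuous(rec, config)
  } else NULL
  med <- NULL
  for (r in seq_len(repetitions)) {
    if (method == "phase") {
      # scramble the continuous band-limited, differentiated EEG right
      # before lag embedding, so the surrogate keeps the processed spectrum
      scont <- cont
      scont$eeg_rec <- phase_scramble(cont$eeg_rec, seed = seeds[r])
      surro <- embed_and_segment(scont, config)
      res <- cross_validate(surro$trials, folds = config$cv_folds,
                            seed = config$seed, outputs = "pc",
                            retained = config$retained_pcs,
                            fold_safe = config$fold_safe,
                            keep_predictions = FALSE)
    } else {
      scr <- fold_scramble(prep$trials, seed = seeds[r])
      res <- cross_validate(scr, folds = config$cv_folds, seed = config$seed,
                            outputs = "pc", retained = config$retained_pcs,
                            fold_safe = config$fold_safe,
                            keep_predictions = FALSE)
    }
    med <- rbind(med, res$median_r)
  }
  rownames(med) <- paste0("rep", seq_len(repetitions))
  structure(list(method = method, repetitions = repetitions,
                 median_r = med, mean = colMeans(med),
                 sem = apply(med, 2, sd) / sqrt(repetitions),
                 seeds = seeds),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> method=%s, %d repetition(s)\n", x$method,
              x$repetitions))
  cat("  mean median-r:", paste(sprintf("%s=%.3f (sem %.3f)", names(x$mean),
                                        x$mean, x$sem), collapse = ", "), "\n")
  invisible(x)
}
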