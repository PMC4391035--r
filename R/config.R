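#' Pipeline configuration
#'
#' All tunable parameters of the analysis, with defaults reproducing the
#' study settings: 0.3-1 Hz zero-phase 4th-order Butterworth band, 100 Hz
#' target rate, 11 lags (0-100 ms in 10 ms steps), 400/100 ms segmentation
#' margins, six excluded peripheral channels, 3 retained synergies, 8-fold
#' cross-validation, RBF widths sigma = {5, 10, 15} over 8 scalp regions,
#' and 5 surrogate repetitions.
#'
#' @param filter_band length-2 numeric, high-pass and low-pass edges in Hz.
#'   A first edge of 0 disables the high-pass.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is squared).
#' @param target_fs decoding sample rate in Hz; must divide the recording
#'   rate.
#' @param max_lag maximum lag L in samples at `target_fs` (L + 1 lag copies).
#' @param lag_step lag step in samples at `target_fs`.
#' @param pre_ms,post_ms segmentation margins: ms before movement onset and
#'   after movement offset.
#' @param excluded_channels labels dropped before decoding.
#' @param retained_pcs number of kinematic synergies decoded.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment and all stochastic
#'   steps.
#' @param roi_map named list, scalp region -> channel labels (classifier
#'   feature blocks).
#' @param sigmas relative RBF width multipliers for the basis kernels.
#' @param svm_cost SVM cost parameter C.
#' @param surrogate_reps repetitions for each surrogate chance-level method.
#' @param fold_safe logical; if `TRUE` (default) feature standardization and
#'   synergy fitting use training folds only. `FALSE` reproduces the
#'   original across-all-trials convention, which leaks summary statistics
#'   across folds.
#' @param class_times_ms classifier window centres, ms relative to movement
#'   onset.
#' @param mkl_tol,mkl_max_iter SimpleMKL stopping controls: relative
#'   objective decrease and outer-iteration cap.
#' @return an object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(filter_band = c(0.3, 1),
                            filter_order = 4L,
                            target_fs = 100,
                            max_lag = 10L,
                            lag_step = 1L,
                            pre_ms = 400,
                            post_ms = 100,
                            excluded_channels = peripheral_channels(),
                            retained_pcs = 3L,
                            cv_folds = 8L,
                            seed = 1L,
                            roi_map = default_roi_map(),
                            sigmas = c(5, 10, 15),
                            svm_cost = 1,
                            surrogate_reps = 5L,
                            fold_safe = TRUE,
                            class_times_ms = seq(-1000, 3000, by = 250),
                            mkl_tol = 1e-3,
                            mkl_max_iter = 40L) {
  cfg <- list(
    filter_band = as.numeric(filter_band), filter_order = as.integer(filter_order),
    target_fs = as.numeric(target_fs), max_lag = as.integer(max_lag),
    lag_step = as.integer(lag_step), pre_ms = as.numeric(pre_ms),
    post_ms = as.numeric(post_ms),
    excluded_channels = as.character(excluded_channels),
    retained_pcs = as.integer(retained_pcs), cv_folds = as.integer(cv_folds),
    seed = as.integer(seed), roi_map = roi_map, sigmas = as.numeric(sigmas),
    svm_cost = as.numeric(svm_cost), surrogate_reps = as.integer(surrogate_reps),
    fold_safe = isTRUE(fold_safe), class_times_ms = as.numeric(class_times_ms),
    mkl_tol = as.numeric(mkl_tol), mkl_max_iter = as.integer(mkl_max_iter)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (length(filter_band) != 2L || any(is.na(filter_band))) {
      stopf("filter_band must be two numbers")
    }
    if (filter_band[1] < 0 || filter_band[2] <= 0 || filter_band[1] >= filter_band[2]) {
      stopf("filter_band edges must satisfy 0 <= low < high")
    }
    if (filter_order < 1L) stopf("filter_order must be positive")
    if (target_fs <= 0) stopf("target_fs must be positive")
    if (max_lag < 0L) stopf("max_lag must be non-negative")
    if (lag_step < 1L) stopf("lag_step must be >= 1")
    if (pre_ms < 0 || post_ms < 0) stopf("segment margins must be non-negative")
    if (retained_pcs < 1L || retained_pcs > 15L) stopf("retained_pcs must be in 1..15")
    if (cv_folds < 2L) stopf("cv_folds must be >= 2")
    if (any(sigmas <= 0)) stopf("sigmas must be positive")
    if (svm_cost <= 0) stopf("svm_cost must be positive")
    if (surrogate_reps < 1L) stopf("surrogate_reps must be >= 1")
  })
  validate_roi_map(cfg$roi_map)
  structure(cfg, class = "pipeline_config")
}

#' Load a configuration from JSON
#'
#' Reads a JSON document of configuration overrides; unspecified keys take
#' the defaults of [pipeline_config()]. The resolved configuration is echoed
#' as a message so runs are reproducible from their logs.
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  base <- pipeline_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(user)) stopf("config must be a JSON object")
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    if (!is.null(user$roi_map)) user$roi_map <- lapply(user$roi_map, as.character)
    base <- utils::modifyList(unclass(base), user)
  }
  cfg <- validate_config(base)
  message("resolved config: ", config_digest(cfg))
  cfg
}

config_digest <- function(cfg) {
  flat <- unclass(cfg)
  flat$roi_map <- NULL
  paste(vapply(names(flat), function(k) {
    paste0(k, "=", paste(format(flat[[k]], digits = 6), collapse = ","))
  }, ""), collapse = " ")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(" ", config_digest(x), "\n")
  cat(sprintf("  roi_map: %d regions / %d channels\n",
              length(x$roi_map), length(unlist(x$roi_map))))
  invisible(x)
}
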