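# Kinematic synergies: PCA of the 15 joint angular velocities. Covariance
# PCA with centering and no per-joint rescaling -- all joints share units
# (deg/s), so the loadings stay interpretable as coordinated multi-joint
# velocity patterns.

#' Fit a synergy model to a trial set
#'
#' Eigen-decomposition of the covariance of the stacked joint-velocity
#' matrix (sum of trial lengths x 15). Columns are ordered by decreasing
#' variance; the sign of each component is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param trials a [segment_trials()] result with joint velocities.
#' @param retained number of components kept for decoding.
#' @return an object of class `synergy_model`: `mean` (15-vector, deg/s),
#'   `loadings` (15 x 15 orthonormal, columns = components),
#'   `variance_fractions` (non-increasing, sums to 1), `retained`,
#'   `joint_labels`.
#' @export
fit_synergies <- function(trials, retained = 3L) {
  stopifnot(inherits(trials, "trial_set"))
  v <- do.call(rbind, lapply(trials$trials, `[[`, "vel"))
  if (is.null(v)) stopf("trial set has no kinematics")
  fit_synergies_matrix(v, retained, trials$joint_labels)
}

fit_synergies_matrix <- function(v, retained, joint_labels) {
  if (nrow(v) <= ncol(v)) {
    stopf("need more than %d samples to fit synergies (got %d)", ncol(v), nrow(v))
  }
  mu <- colMeans(v)
  e <- eigen(cov(v), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  w <- e$vectors
  for (j in seq_len(ncol(w))) {
    if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
  }
  dimnames(w) <- list(joint_labels, paste0("PC", seq_len(ncol(w))))
  names(mu) <- joint_labels
  structure(list(mean = mu, loadings = w,
                 variance_fractions = vals / sum(vals),
                 retained = as.integer(retained),
                 joint_labels = joint_labels),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  vf <- x$variance_fractions
  cat(sprintf("<synergy_model> %d joints, %d retained component(s)\n",
              length(x$mean), x$retained))
  cat(sprintf("  variance: %s (first %d sum %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * vf[seq_len(min(5, length(vf)))]),
                    collapse = " "),
              x$retained, 100 * sum(vf[seq_len(x$retained)])))
  invisible(x)
}

#' Project trial kinematics onto the retained synergies
#'
#' Fills each trial's `pc` field with `(velocities - mean) %*%
#' loadings[, 1..retained]`. Projection with all 15 components is lossless;
#' see [reconstruct_velocities()].
#'
#' @param trials a `trial_set` with joint velocities.
#' @param model a fitted [fit_synergies()] model.
#' @return the trial set with per-trial component trajectories.
#' @export
project_synergies <- function(trials, model) {
  stopifnot(inherits(trials, "trial_set"), inherits(model, "synergy_model"))
  if (!identical(trials$joint_labels, model$joint_labels)) {
    stopf("joint labels of the trial set do not match the synergy model")
  }
  w <- model$loadings[, seq_len(model$retained), drop = FALSE]
  for (i in seq_along(trials$trials)) {
    v <- trials$trials[[i]]$vel
    trials$trials[[i]]$pc <- sweep(v, 2, model$mean) %*% w
  }
  trials$synergy <- model
  trials
}

#' Reconstruct joint velocities from synergy scores
#'
#' Inverse of the projection: with all 15 components the reconstruction is
#' exact; with the retained subset it is the low-rank approximation.
#'
#' @param model a [fit_synergies()] model.
#' @param scores samples x components score matrix.
#' @return samples x 15 joint-velocity matrix.
#' @export
reconstruct_velocities <- function(model, scores) {
  k <- ncol(scores)
  sweep(scores %*% t(model$loadings[, seq_len(k), drop = FALSE]), 2,
        model$mean, "+")
}
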