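# Lagged linear (Wiener) decoder: ordinary least squares from flattened
# (channel, lag) EEG features onto kinematic outputs, solved through the
# normal equations. Cross-validation caches per-fold moment matrices
# (X'X, X'V, sums) so that training-fold Grams are obtained by subtraction
# and channel-subset re-decodes reduce to sub-matrix solves.

# trial feature matrix: time x (channel * lag), lag varying fastest
trial_X <- function(tr, channel_idx = NULL) {
  e <- tr$eeg
  if (!is.null(channel_idx)) e <- e[, channel_idx, , drop = FALSE]
  d <- dim(e)
  m <- aperm(e, c(1, 3, 2))
  dim(m) <- c(d[1], d[2] * d[3])
  m
}

feature_cols <- function(channel_idx, n_lags) {
  as.vector(outer(seq_len(n_lags), (channel_idx - 1) * n_lags, `+`))
}

fold_moments <- function(trials, fold_of, n_folds) {
  p <- length(trials$channel_labels) * (trials$L + 1L)
  nv <- if (is.null(trials$trials[[1]]$vel)) 0L else ncol(trials$trials[[1]]$vel)
  blank <- function() list(n = 0, sx = numeric(p), sxx = matrix(0, p, p),
                           sv = numeric(nv), svv = matrix(0, nv, nv),
                           sxv = matrix(0, p, nv))
  mom <- lapply(seq_len(n_folds), function(i) blank())
  for (i in seq_along(trials$trials)) {
    f <- fold_of[i]
    x <- trial_X(trials$trials[[i]])
    mom[[f]]$n <- mom[[f]]$n + nrow(x)
    mom[[f]]$sx <- mom[[f]]$sx + colSums(x)
    mom[[f]]$sxx <- mom[[f]]$sxx + crossprod(x)
    if (nv > 0L) {
      v <- trials$trials[[i]]$vel
      mom[[f]]$sv <- mom[[f]]$sv + colSums(v)
      mom[[f]]$svv <- mom[[f]]$svv + crossprod(v)
      mom[[f]]$sxv <- mom[[f]]$sxv + crossprod(x, v)
    }
  }
  mom
}

sum_moments <- function(moms) {
  Reduce(function(a, b) {
    list(n = a$n + b$n, sx = a$sx + b$sx, sxx = a$sxx + b$sxx,
         sv = a$sv + b$sv, svv = a$svv + b$svv, sxv = a$sxv + b$sxv)
  }, moms)
}

# centered, scaled normal-equations solve; minimum-norm fallback when the
# design is rank deficient (generic for band-limited EEG, whose lag copies
# are near-collinear). Deficiency is flagged on the result so callers can
# warn once instead of once per fold.
solve_normal_eq <- function(gram_c, cross_c, sd_x) {
  sd_safe <- ifelse(sd_x > 0, sd_x, 1)
  a <- gram_c / tcrossprod(sd_safe)
  b <- cross_c / sd_safe
  deficient <- FALSE
  beta_s <- tryCatch(
    chol2inv(chol(a)) %*% b,
    error = function(e) {
      deficient <<- TRUE
      ev <- eigen(a, symmetric = TRUE)
      keep <- ev$values > max(ev$values, 0) * 1e-10
      if (!any(keep)) return(matrix(0, nrow(a), ncol(b)))
      ev$vectors[, keep, drop = FALSE] %*%
        (crossprod(ev$vectors[, keep, drop = FALSE], b) / ev$values[keep])
    }
  )
  structure(beta_s / sd_safe, deficient = deficient)
}

# regression of the requested outputs on the features, from moment matrices
ols_from_moments <- function(mom, outputs, synergy = NULL, feature_idx = NULL) {
  n <- mom$n
  idx <- feature_idx %||% seq_along(mom$sx)
  mu_x <- mom$sx[idx] / n
  gram_c <- mom$sxx[idx, idx, drop = FALSE] - n * tcrossprod(mu_x)
  var_x <- pmax(diag(gram_c), 0) / (n - 1)
  mu_v <- mom$sv / n
  if (outputs == "pc") {
    w <- synergy$loadings[, seq_len(synergy$retained), drop = FALSE]
    mu_y <- as.numeric(crossprod(w, mu_v - synergy$mean))
    cross_c <- (mom$sxv[idx, , drop = FALSE] - n * tcrossprod(mu_x, mu_v)) %*% w
    out_names <- colnames(w)
  } else {
    mu_y <- mu_v
    cross_c <- mom$sxv[idx, , drop = FALSE] - n * tcrossprod(mu_x, mu_v)
    out_names <- names(mu_v) %||% paste0("joint", seq_along(mu_v))
  }
  beta <- solve_normal_eq(gram_c, cross_c, sqrt(var_x))
  intercept <- mu_y - as.numeric(crossprod(beta, mu_x))
  list(beta = beta, intercept = intercept, out_names = out_names,
       mu_v = mu_v, synergy = synergy,
       deficient = isTRUE(attr(beta, "deficient")))
}

observed_outputs <- function(tr, outputs, synergy) {
  if (outputs == "pc") {
    w <- synergy$loadings[, seq_len(synergy$retained), drop = FALSE]
    sweep(tr$vel, 2, synergy$mean) %*% w
  } else {
    tr$vel
  }
}

#' Fit a Wiener decoding model
#'
#' Ordinary least squares of each output (retained synergy components or the
#' 15 joint velocities) on the flattened (channel, lag) EEG features plus an
#' intercept, solved per output through the normal equations; a
#' rank-deficient design falls back to the minimum-norm solution with a
#' warning.
#'
#' @param trials a `trial_set` (features standardized upstream for the
#'   canonical pipeline).
#' @param outputs `"pc"` (synergy components; default) or `"joints"`.
#' @param synergy a fitted [fit_synergies()] model; fitted from `trials`
#'   when omitted and `outputs = "pc"`.
#' @return an object of class `wiener_model`: `coef` (channels x lags x
#'   outputs array), `intercepts`, `channel_labels`, `L`, `output_names`.
#' @export
fit_wiener <- function(trials, outputs = c("pc", "joints"), synergy = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  outputs <- match.arg(outputs)
  if (outputs == "pc" && is.null(synergy)) synergy <- fit_synergies(trials)
  mom <- sum_moments(fold_moments(trials, rep(1L, length(trials$trials)), 1L))
  min_rows <- length(mom$sx) + 1L
  if (mom$n < min_rows) {
    stopf("need at least %d training samples for %d features", min_rows,
          length(mom$sx))
  }
  fit <- ols_from_moments(mom, outputs, synergy)
  if (fit$deficient) {
    warnf("rank-deficient design: using the minimum-norm least-squares solution")
  }
  nc <- length(trials$channel_labels); nl <- trials$L + 1L
  coef_arr <- array(fit$beta, dim = c(nl, nc, length(fit$out_names)),
                    dimnames = list(paste0("lag", (0:trials$L) * trials$step),
                                    trials$channel_labels, fit$out_names))
  coef_arr <- aperm(coef_arr, c(2, 1, 3))
  structure(list(coef = coef_arr, intercepts = setNames(fit$intercept, fit$out_names),
                 channel_labels = trials$channel_labels, L = trials$L,
                 step = trials$step, fs = trials$fs, output_names = fit$out_names,
                 outputs = outputs, synergy = fit$synergy,
                 beta_flat = fit$beta),
            class = "wiener_model")
}

#' @export
print.wiener_model <- function(x, ...) {
  cat(sprintf("<wiener_model> %d channel(s) x %d lag(s) -> %s\n",
              length(x$channel_labels), x$L + 1L,
              paste(x$output_names, collapse = ", ")))
  invisible(x)
}

#' Predict kinematic trajectories from a fitted Wiener model
#'
#' Applies the decoding equation `y_i[t] = b0_i + sum_n sum_k b_nki *
#' EEG_n[t - k]` to every trial. Deterministic; the trial features must use
#' the channel/lag layout of the model.
#'
#' @param object a [fit_wiener()] model.
#' @param trials a `trial_set` with matching layout.
#' @param ... unused.
#' @return list of per-trial predicted matrices (time x outputs).
#' @export
predict.wiener_model <- function(object, trials, ...) {
  stopifnot(inherits(trials, "trial_set"))
  if (!identical(trials$channel_labels, object$channel_labels) ||
      trials$L != object$L) {
    stopf("trial feature layout does not match the model")
  }
  lapply(trials$trials, function(tr) {
    p <- trial_X(tr) %*% object$beta_flat
    p <- sweep(p, 2, object$intercepts, "+")
    colnames(p) <- object$output_names
    p
  })
}

assign_folds <- function(labels, folds, seed) {
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      ids <- sample(which(labels == lab))
      # random starting fold per class so short classes do not all pile
      # into the first folds
      offset <- sample.int(folds, 1L) - 1L
      fold_of[ids] <- (offset + seq_along(ids) - 1L) %% folds + 1L
    }
  })
  fold_of
}

#' Cross-validated decoding accuracy
#'
#' Stratified, seeded k-fold cross-validation of the Wiener decoder: per
#' fold, the model is fitted on the remaining folds and applied to the test
#' fold; accuracy is the Pearson correlation between predicted and observed
#' values over the concatenated test samples, reported per fold with the
#' median across folds. In fold-safe mode (default) the synergy model is
#' refitted on each training fold; otherwise a single model fitted across
#' all trials is used, reproducing the original convention at the cost of a
#' leak across folds.
#'
#' @param trials a `trial_set` with kinematics.
#' @param folds number of folds.
#' @param seed seed for the stratified fold assignment.
#' @param outputs `"pc"` or `"joints"`.
#' @param retained synergy components decoded when `outputs = "pc"`.
#' @param fold_safe logical, see above.
#' @param synergy optional global synergy model (required when
#'   `fold_safe = FALSE` unless it should be fitted here).
#' @param channel_subset optional channel indices (into
#'   `trials$channel_labels`) restricting the decoder.
#' @param moments precomputed [fold_moments()] (internal reuse).
#' @param fold_of precomputed fold assignment (internal reuse).
#' @param keep_predictions keep per-trial predicted/observed trajectories.
#' @return an object of class `decoding_result`: `r` (folds x outputs),
#'   `median_r`, `fold_of`, `n_test` (samples per fold), and optionally
#'   `predictions` / `observed`.
#' @export
cross_validate <- function(trials, folds = 8L, seed = 1L,
                           outputs = c("pc", "joints"), retained = 3L,
                           fold_safe = TRUE, synergy = NULL,
                           channel_subset = NULL, moments = NULL,
                           fold_of = NULL, keep_predictions = TRUE) {
  stopifnot(inherits(trials, "trial_set"))
  outputs <- match.arg(outputs)
  n_trials <- length(trials$trials)
  if (n_trials < folds) stopf("need at least %d trials for %d folds", folds, folds)
  labels <- trial_labels(trials)
  if (is.null(fold_of)) fold_of <- assign_folds(labels, folds, seed)
  if (is.null(moments)) moments <- fold_moments(trials, fold_of, folds)
  feature_idx <- if (is.null(channel_subset)) NULL else {
    feature_cols(channel_subset, trials$L + 1L)
  }
  if (outputs == "pc" && !fold_safe && is.null(synergy)) {
    synergy <- fit_synergies(trials, retained = retained)
  }
  n_out <- if (outputs == "pc") retained else length(moments[[1]]$sv)
  r_mat <- matrix(NA_real_, folds, n_out)
  n_test <- integer(folds)
  preds <- if (keep_predictions) vector("list", n_trials) else NULL
  obs_l <- if (keep_predictions) vector("list", n_trials) else NULL
  out_names <- NULL
  n_deficient <- 0L
  for (f in seq_len(folds)) {
    train_mom <- sum_moments(moments[-f])
    syn_f <- if (outputs == "pc") {
      if (fold_safe) {
        mu_v <- train_mom$sv / train_mom$n
        cov_v <- (train_mom$svv - train_mom$n * tcrossprod(mu_v)) / (train_mom$n - 1)
        syn <- fit_synergies_cov(mu_v, cov_v, retained, trials$joint_labels)
        syn
      } else synergy
    } else NULL
    fit <- ols_from_moments(train_mom, outputs, syn_f, feature_idx)
    if (fit$deficient) n_deficient <- n_deficient + 1L
    out_names <- fit$out_names
    test_ids <- which(fold_of == f)
    if (!length(test_ids)) {
      warnf("fold %d is empty: no test trials, r recorded as NA", f)
      n_test[f] <- 0L
      next
    }
    pred_all <- NULL; obs_all <- NULL
    for (i in test_ids) {
      tr <- trials$trials[[i]]
      x <- trial_X(tr, channel_subset)
      p <- sweep(x %*% fit$beta, 2, fit$intercept, "+")
      o <- observed_outputs(tr, outputs, syn_f)
      if (keep_predictions) {
        colnames(p) <- out_names
        preds[[i]] <- p; obs_l[[i]] <- o
      }
      pred_all <- rbind(pred_all, p); obs_all <- rbind(obs_all, o)
    }
    n_test[f] <- nrow(pred_all)
    for (j in seq_len(n_out)) {
      sp <- sd(pred_all[, j]); so <- sd(obs_all[, j])
      if (!is.finite(sp) || sp == 0 || !is.finite(so) || so == 0) {
        warnf("fold %d output %d: zero-variance prediction, r recorded as 0", f, j)
        r_mat[f, j] <- 0
      } else {
        r_mat[f, j] <- cor(pred_all[, j], obs_all[, j])
      }
    }
  }
  colnames(r_mat) <- out_names
  if (n_deficient > 0L) {
    message(sprintf("%d of %d fold fit(s) used the minimum-norm solution (rank-deficient design)",
                    n_deficient, folds))
  }
  structure(list(r = r_mat, median_r = apply(r_mat, 2, median, na.rm = TRUE),
                 fold_of = fold_of, n_test = n_test, outputs = outputs,
                 trial_labels = labels,
                 predictions = preds, observed = obs_l),
            class = "decoding_result")
}

# synergy model from first/second moments (fold-safe refit without
# re-stacking the velocity matrix)
fit_synergies_cov <- function(mu_v, cov_v, retained, joint_labels) {
  e <- eigen(cov_v, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  w <- e$vectors
  for (j in seq_len(ncol(w))) {
    if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
  }
  dimnames(w) <- list(joint_labels, paste0("PC", seq_len(ncol(w))))
  names(mu_v) <- joint_labels
  structure(list(mean = mu_v, loadings = w,
                 variance_fractions = vals / sum(vals),
                 retained = as.integer(retained), joint_labels = joint_labels),
            class = "synergy_model")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d fold(s), outputs: %s\n", nrow(x$r),
              paste(colnames(x$r), collapse = ", ")))
  cat("  median r:", paste(sprintf("%s=%.3f", names(x$median_r), x$median_r),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Rank channels by their decoding weight
#'
#' For each channel n, `R_n` is the mean over lags of the Euclidean norm of
#' its coefficients across the three synergy outputs, computed from a model
#' fitted on the entire dataset. Channels are ordered by decreasing `R_n`,
#' ties broken by channel index.
#'
#' @param model a [fit_wiener()] model over at least three synergy outputs.
#' @return an object of class `channel_ranking`: `R_n` (named), `order`
#'   (permutation of channel indices), `labels_ranked`.
#' @export
rank_channels <- function(model) {
  stopifnot(inherits(model, "wiener_model"))
  if (dim(model$coef)[3] < 3L) {
    stopf("channel ranking requires the three synergy outputs (got %d)",
          dim(model$coef)[3])
  }
  b <- model$coef[, , 1:3, drop = FALSE]
  r_n <- apply(sqrt(apply(b^2, c(1, 2), sum)), 1, mean)
  names(r_n) <- model$channel_labels
  ord <- order(-r_n, seq_along(r_n))
  structure(list(R_n = r_n, order = ord,
                 labels_ranked = model$channel_labels[ord]),
            class = "channel_ranking")
}

#' Per-lag contribution percentages
#'
#' `%T_k`: the share of the summed coefficient magnitude
#' `sqrt(sum_i beta_nki^2)` carried by lag k, in percent (summing to 100),
#' plus the unnormalized channel x lag map for topographic plotting.
#'
#' @param model a [fit_wiener()] model over the synergy outputs.
#' @return an object of class `lag_contribution`: `percent` (named by lag
#'   ms), `map` (channels x lags).
#' @export
lag_contributions <- function(model) {
  stopifnot(inherits(model, "wiener_model"))
  map <- sqrt(apply(model$coef^2, c(1, 2), sum))
  total <- sum(map)
  if (total == 0) stopf("all coefficients are zero: contributions undefined")
  pct <- 100 * colSums(map) / total
  lag_ms <- round((0:model$L) * model$step * 1000 / model$fs)
  names(pct) <- sprintf("-%dms", lag_ms)
  structure(list(percent = pct, map = map), class = "lag_contribution")
}

#' Decoding accuracy as a function of channel count
#'
#' Re-runs the cross-validated decoder with the best N channels (N = 1 to
#' the channel count) according to a [rank_channels()] ranking, then fits a
#' double exponential `a*exp(b*N) + c*exp(d*N)` to each output's median-r
#' curve to locate the accuracy peak robustly.
#'
#' @param trials a `trial_set` with kinematics.
#' @param ranking a [rank_channels()] result over the same channels.
#' @param folds,seed,retained,fold_safe,synergy as in [cross_validate()].
#' @return an object of class `accuracy_curve`: `curve` (N x outputs median
#'   r), `fits` (per output: parameters, fitted values), `peak_n`, `peak_r`.
#' @export
accuracy_vs_channels <- function(trials, ranking, folds = 8L, seed = 1L,
                                 retained = 3L, fold_safe = TRUE,
                                 synergy = NULL) {
  stopifnot(inherits(trials, "trial_set"), inherits(ranking, "channel_ranking"))
  if (length(ranking$R_n) != length(trials$channel_labels)) {
    stopf("ranking covers %d channels but trials have %d",
          length(ranking$R_n), length(trials$channel_labels))
  }
  nc <- length(trials$channel_labels)
  labels <- trial_labels(trials)
  fold_of <- assign_folds(labels, folds, seed)
  moments <- fold_moments(trials, fold_of, folds)
  if (!fold_safe && is.null(synergy)) synergy <- fit_synergies(trials, retained)
  curve <- NULL
  for (n_ch in seq_len(nc)) {
    res <- cross_validate(trials, folds = folds, seed = seed, outputs = "pc",
                          retained = retained, fold_safe = fold_safe,
                          synergy = synergy,
                          channel_subset = ranking$order[seq_len(n_ch)],
                          moments = moments, fold_of = fold_of,
                          keep_predictions = FALSE)
    curve <- rbind(curve, res$median_r)
  }
  rownames(curve) <- seq_len(nc)
  fits <- lapply(seq_len(ncol(curve)), function(j) {
    fit_double_exponential(curve[, j], seed = seed + j)
  })
  names(fits) <- colnames(curve)
  structure(list(curve = curve,
                 fits = fits,
                 peak_n = vapply(fits, `[[`, 0L, "peak_n"),
                 peak_r = vapply(fits, `[[`, 0, "peak_r"),
                 ranking = ranking),
            class = "accuracy_curve")
}

#' Fit a double exponential to an accuracy curve
#'
#' Nonlinear least squares of `y ~ a*exp(b*N) + c*exp(d*N)` on N = 1..len,
#' via Levenberg-Marquardt from multiple seeded starts spanning the sign
#' patterns of the rise-and-saturate shape. The peak is the integer argmax
#' of the fitted curve; if no start converges, the argmax of the raw curve
#' is returned with a warning.
#'
#' @param y numeric accuracy curve indexed by channel count.
#' @param seed seed for the start jitter.
#' @param n_starts number of starting points.
#' @return list with `pars` (a, b, c, d or NULL), `fitted`, `peak_n`,
#'   `peak_r`, `converged`.
#' @export
fit_double_exponential <- function(y, seed = 1L, n_starts = 8L) {
  n <- length(y)
  df <- data.frame(N = seq_len(n), y = y)
  scale_y <- max(abs(y), 1e-6)
  base_starts <- list(
    c(a = scale_y, b = -0.005, c = -scale_y, d = -0.3),
    c(a = scale_y, b = -0.02, c = -scale_y, d = -0.6),
    c(a = scale_y, b = 0.001, c = -scale_y, d = -0.2),
    c(a = 2 * scale_y, b = -0.01, c = -2 * scale_y, d = -0.8)
  )
  best <- NULL; best_sse <- Inf
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      st <- base_starts[[(s - 1L) %% length(base_starts) + 1L]]
      if (s > length(base_starts)) {
        st <- st * (1 + 0.3 * rnorm(4))
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(b * N) + c * exp(d * N), data = df,
                          start = as.list(st),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (!is.null(fit)) {
        sse <- sum(residuals(fit)^2)
        if (is.finite(sse) && sse < best_sse) {
          best_sse <- sse; best <- fit
        }
      }
    }
  })
  if (is.null(best)) {
    warnf("double-exponential fit did not converge: falling back to the raw argmax")
    return(list(pars = NULL, fitted = y, peak_n = which.max(y),
                peak_r = max(y), converged = FALSE))
  }
  pars <- coef(best)
  fitted_y <- pars["a"] * exp(pars["b"] * df$N) + pars["c"] * exp(pars["d"] * df$N)
  list(pars = pars, fitted = fitted_y, peak_n = which.max(fitted_y),
       peak_r = max(fitted_y), converged = TRUE)
}

#' Significance of cross-validated correlations
#'
#' Two-sided p-value of each fold's Pearson r under the t-distribution null
#' (`t = r * sqrt((n-2)/(1-r^2))` with the fold's test sample count),
#' Bonferroni-multiplied by `n_comparisons` and capped at 1.
#'
#' @param result a [cross_validate()] result.
#' @param n_comparisons Bonferroni factor (subjects x outputs x channel sets
#'   x folds in the original analysis).
#' @return list with `p` (folds x outputs corrected p-values) and
#'   `median_p` per output.
#' @export
assess_significance <- function(result, n_comparisons = 1L) {
  stopifnot(inherits(result, "decoding_result"))
  if (any(result$n_test < 3L)) stopf("test folds must contain at least 3 samples")
  p <- result$r
  for (f in seq_len(nrow(p))) {
    n <- result$n_test[f]
    r <- result$r[f, ]
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p[f, ] <- pmin(1, 2 * pt(-abs(tt), df = n - 2) * n_comparisons)
  }
  list(p = p, median_p = apply(p, 2, median))
}
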