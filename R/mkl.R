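# Multiple-kernel grasp classification. Basis kernels are RBFs on the
# lagged-EEG feature block of each scalp region (8 regions x 3 relative
# widths = 24 kernels); SimpleMKL learns simplex weights d_m over them by
# reduced-gradient descent on the SVM objective, the inner SVM dual being
# solved as a QP (kernlab::ipop).

roi_feature_blocks <- function(channel_labels, roi_map, n_lags) {
  validate_roi_map(roi_map, channel_labels)
  lapply(roi_map, function(chs) {
    feature_cols(match(chs, channel_labels), n_lags)
  })
}

#' Build the ROI x sigma basis kernels
#'
#' For every scalp region and every relative width sigma, an RBF kernel
#' `K(x_i, x_j) = exp(-||x_i - x_j||^2 / (2 (sigma s)^2))` restricted to the
#' region's (channel, lag) feature block, where `s` is the median pairwise
#' distance within that block on the training set (the data-derived width
#' scale that makes sigma "relative").
#'
#' @param x training feature matrix, samples x (channel * lag) features in
#'   decoder layout.
#' @param roi_blocks feature-column blocks per region, from the internal
#'   ROI map resolution (`roi_feature_blocks`).
#' @param sigmas relative width multipliers.
#' @return an object of class `kernel_set`: `kernels` (list of n x n
#'   matrices), `meta` (region, sigma, scale per kernel), `x`, `roi_blocks`,
#'   `sigmas`.
#' @export
build_kernels <- function(x, roi_blocks, sigmas = c(5, 10, 15)) {
  if (nrow(x) < 2L) stopf("need at least 2 samples to build kernels")
  kernels <- list(); meta <- NULL
  for (roi in names(roi_blocks)) {
    cols <- roi_blocks[[roi]]
    d <- as.matrix(dist(x[, cols, drop = FALSE]))
    s <- median(d[upper.tri(d)])
    if (!is.finite(s) || s <= 0) {
      warnf("ROI %s: zero median pairwise distance, flooring the width scale", roi)
      s <- sqrt(.Machine$double.eps)
    }
    for (sg in sigmas) {
      k <- exp(-d^2 / (2 * (sg * s)^2))
      dimnames(k) <- NULL
      kernels[[length(kernels) + 1L]] <- k
      meta <- rbind(meta, data.frame(roi = roi, sigma = sg, scale = s))
    }
  }
  structure(list(kernels = kernels, meta = meta, x = x,
                 roi_blocks = roi_blocks, sigmas = sigmas),
            class = "kernel_set")
}

# cross kernels between new samples and the training set of a kernel_set
kernel_cross <- function(kset, x_new) {
  out <- vector("list", length(kset$kernels))
  for (m in seq_along(kset$kernels)) {
    roi <- kset$meta$roi[m]; sg <- kset$meta$sigma[m]; s <- kset$meta$scale[m]
    cols <- kset$roi_blocks[[roi]]
    a <- x_new[, cols, drop = FALSE]; b <- kset$x[, cols, drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    out[[m]] <- exp(-pmax(d2, 0) / (2 * (sg * s)^2))
  }
  out
}

combine_kernels <- function(kernels, d) {
  k <- kernels[[1]] * d[1]
  for (m in seq_along(kernels)[-1]) if (d[m] > 0) k <- k + d[m] * kernels[[m]]
  k
}

# C-SVC dual for a fixed kernel matrix, via interior-point QP
solve_svm_dual <- function(k, y, C) {
  n <- length(y)
  h <- tcrossprod(y) * k
  diag_scale <- mean(diag(h))
  jit <- 1e-10 * diag_scale
  sol <- NULL
  for (attempt in 1:6) {
    sol <- tryCatch(
      kernlab::ipop(c = matrix(-1, n, 1), H = h + diag(jit, n),
                    A = matrix(y, 1, n), b = 0, l = matrix(0, n, 1),
                    u = matrix(C, n, 1), r = 0, sigf = 9, maxiter = 80),
      error = function(e) NULL)
    if (!is.null(sol)) break
    jit <- jit * 1000
    if (attempt >= 3) {
      warnf("combined kernel numerically singular; jitter %.1e added", jit)
    }
  }
  if (is.null(sol)) stopf("SVM dual QP failed even with jitter")
  alpha <- pmin(pmax(as.numeric(kernlab::primal(sol)), 0), C)
  ay <- alpha * y
  f0 <- as.numeric(k %*% ay)
  tol_a <- 1e-6 * C
  margin_sv <- which(alpha > tol_a & alpha < C - tol_a)
  b <- if (length(margin_sv)) {
    mean(y[margin_sv] - f0[margin_sv])
  } else {
    up <- f0[y > 0 & alpha < C - tol_a]; dn <- f0[y < 0 & alpha < C - tol_a]
    if (length(up) && length(dn)) -(max(dn) + min(up)) / 2 else 0
  }
  list(alpha = alpha, ay = ay, b = b,
       objective = sum(alpha) - 0.5 * sum(ay * (k %*% ay)))
}

simplemkl_binary <- function(kernels, y, C, tol, max_iter) {
  m_k <- length(kernels)
  d <- rep(1 / m_k, m_k)
  sol <- solve_svm_dual(combine_kernels(kernels, d), y, C)
  obj <- sol$objective
  trace <- obj
  for (iter in seq_len(max_iter)) {
    grad <- vapply(kernels, function(km) -0.5 * sum(sol$ay * (km %*% sol$ay)), 0)
    mu <- which.max(d)
    red <- grad - grad[mu]
    dir <- -red
    dir[d <= 1e-12 & red > 0] <- 0
    dir[mu] <- 0
    dir[mu] <- -sum(dir)
    if (max(abs(dir)) < 1e-12) break
    neg <- dir < -1e-15
    gamma_max <- if (any(neg)) min(-d[neg] / dir[neg]) else 0
    if (gamma_max <= 0) break
    gamma <- gamma_max
    improved <- FALSE
    for (ls in 1:12) {
      d_try <- pmax(d + gamma * dir, 0)
      d_try <- d_try / sum(d_try)
      sol_try <- solve_svm_dual(combine_kernels(kernels, d_try), y, C)
      if (sol_try$objective < obj - 1e-12 * max(1, abs(obj))) {
        d <- d_try; sol <- sol_try
        improved <- TRUE
        break
      }
      gamma <- gamma / 2
    }
    if (!improved) break
    rel_drop <- (obj - sol$objective) / max(abs(obj), .Machine$double.eps)
    obj <- sol$objective
    trace <- c(trace, obj)
    if (rel_drop < tol) break
  }
  list(d = d, alpha = sol$alpha, ay = sol$ay, b = sol$b,
       objective = obj, obj_trace = trace)
}

#' Train a SimpleMKL grasp classifier
#'
#' Alternating optimization: for fixed simplex weights d the SVM dual is
#' solved exactly; a reduced-gradient step on d (within the probability
#' simplex) follows, with a backtracking line search that only accepts
#' objective decreases, so the objective is non-increasing across outer
#' iterations. Multiclass problems use one-vs-rest with kernel weights
#' learned per binary problem.
#'
#' @param kset a [build_kernels()] result on the training samples.
#' @param labels factor (or character) of training labels, >= 2 classes.
#' @param cost SVM cost parameter C.
#' @param tol relative objective-decrease stopping tolerance.
#' @param max_iter outer-iteration cap (the best iterate is returned if it
#'   is hit).
#' @return an object of class `simplemkl`: per-class binary fits (support
#'   coefficients, bias, simplex weights `d`, objective trace), class
#'   levels, and the kernel set.
#' @export
train_simplemkl <- function(kset, labels, cost = 1, tol = 1e-3, max_iter = 40L) {
  stopifnot(inherits(kset, "kernel_set"))
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stopf("need at least 2 classes")
  if (length(labels) != nrow(kset$x)) stopf("labels/kernel sample mismatch")
  lv <- levels(labels)
  fits <- if (nlevels(labels) == 2L) {
    y <- ifelse(labels == lv[1], 1, -1)
    list(simplemkl_binary(kset$kernels, y, cost, tol, max_iter))
  } else {
    lapply(lv, function(cl) {
      y <- ifelse(labels == cl, 1, -1)
      simplemkl_binary(kset$kernels, y, cost, tol, max_iter)
    })
  }
  structure(list(fits = fits, levels = lv, kset = kset, cost = cost),
            class = "simplemkl")
}

#' Predict grasp classes with a SimpleMKL classifier
#'
#' @param object a [train_simplemkl()] fit.
#' @param x_new new samples x features matrix (decoder feature layout).
#' @param ... unused.
#' @return list with `class` (factor) and `decision` (samples x classes or
#'   single column for binary problems).
#' @export
predict.simplemkl <- function(object, x_new, ...) {
  cross <- kernel_cross(object$kset, x_new)
  dec <- vapply(object$fits, function(f) {
    as.numeric(combine_kernels(cross, f$d) %*% f$ay + f$b)
  }, numeric(nrow(x_new)))
  dec <- matrix(dec, nrow = nrow(x_new))
  if (length(object$fits) == 1L) {
    cls <- ifelse(dec[, 1] >= 0, object$levels[1], object$levels[2])
  } else {
    cls <- object$levels[max.col(dec, ties.method = "first")]
  }
  list(class = factor(cls, levels = object$levels), decision = dec)
}

#' Classify EEG windows at a fixed time relative to movement onset
#'
#' Each trial contributes one feature vector: the lagged (channel x lag)
#' EEG sample at `onset + time_ms`, standardized with the same statistics
#' as the decoder features and split into ROI blocks. Stratified k-fold
#' cross-validation with a SimpleMKL classifier per fold; test predictions
#' are pooled into a single confusion matrix (rows = measured grasp,
#' columns = predicted grasp). Trials whose window (or lag history) falls
#' outside the recording are excluded and counted.
#'
#' @param prep a [preprocess_recording()] result.
#' @param time_ms window time in ms relative to movement onset.
#' @param config a [pipeline_config()].
#' @param fstats optional precomputed feature statistics (mean/sd
#'   matrices); computed from the segmented trials when omitted.
#' @param permute_labels permute trial labels before cross-validation
#'   (chance-level control).
#' @return a `confusion_matrix` (integer matrix with class labels), with
#'   attributes `n_excluded` and `accuracy`.
#' @export
classify_windows <- function(prep, time_ms, config = pipeline_config(),
                             fstats = NULL, permute_labels = FALSE) {
  stopifnot(inherits(prep, "preprocessed_recording"))
  if (is.null(fstats)) fstats <- feature_stats(prep$trials)
  lag <- prep$lagged
  fs <- lag$fs
  n <- dim(lag$data)[1]
  idx <- prep$events$onset + as.integer(round(time_ms / 1000 * fs))
  valid <- idx >= lag$valid_from & idx <= n
  if (sum(valid) < config$cv_folds) {
    stopf("only %d trial(s) have a window at %d ms", sum(valid), time_ms)
  }
  labels <- factor(prep$events$label[valid])
  if (nlevels(labels) < 2L) stopf("fewer than 2 classes present at %d ms", time_ms)
  classes <- sort(unique(prep$events$label))
  sd_safe <- ifelse(fstats$sd > 0, fstats$sd, 1)
  feats <- t(vapply(idx[valid], function(i) {
    m <- (lag$data[i, , ] - fstats$mean) / sd_safe
    as.vector(t(m))
  }, numeric(length(lag$channel_labels) * (lag$L + 1L))))
  if (permute_labels) {
    labels <- with_seed(config$seed + as.integer(time_ms), sample(labels))
  }
  blocks <- roi_feature_blocks(lag$channel_labels, config$roi_map, lag$L + 1L)
  fold_of <- assign_folds(as.character(labels), config$cv_folds, config$seed)
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(measured = classes, predicted = classes))
  for (f in seq_len(config$cv_folds)) {
    tr_i <- fold_of != f; te_i <- fold_of == f
    if (!any(te_i)) next
    kset <- build_kernels(feats[tr_i, , drop = FALSE], blocks, config$sigmas)
    fit <- train_simplemkl(kset, droplevels(labels[tr_i]), cost = config$svm_cost,
                           tol = config$mkl_tol, max_iter = config$mkl_max_iter)
    pr <- predict(fit, feats[te_i, , drop = FALSE])
    for (k in seq_along(which(te_i))) {
      i <- which(te_i)[k]
      cm[as.character(labels[i]), as.character(pr$class[k])] <-
        cm[as.character(labels[i]), as.character(pr$class[k])] + 1L
    }
  }
  attr(cm, "n_excluded") <- sum(!valid)
  attr(cm, "accuracy") <- sum(diag(cm)) / sum(cm)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Mutual information of a confusion matrix
#'
#' Information (bits) conveyed about the grasp type by the classifier
#' output: `I = sum P(PG, MG) log2 [P(PG, MG) / (P(PG) P(MG))]` with the
#' joint distribution taken from the normalized confusion counts and
#' `0 log 0 = 0`. Bounded by log2 of the class count.
#'
#' @param cm confusion matrix of counts (rows = measured, columns =
#'   predicted).
#' @return information in bits.
#' @export
information_content <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stopf("empty confusion matrix")
  p <- cm / total
  pr <- rowSums(p); pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  sum(terms[p > 0])
}

#' Information-over-time analysis
#'
#' Runs [classify_windows()] at each requested time relative to movement
#' onset and converts the pooled confusion matrix into bits of information
#' about the grasp type. Times at which too few trials or classes are
#' available are recorded as `NA` (with the reason logged); it is an error
#' if every time point fails.
#'
#' @param prep a [preprocess_recording()] result.
#' @param config a [pipeline_config()].
#' @param times_ms window times in ms (default from the config: -1000 to
#'   3000 in 250 ms steps).
#' @return an object of class `information_timeline`: `time_ms`, `bits`,
#'   `n_trials`, `accuracy`, `confusions` (list).
#' @export
information_timeline <- function(prep, config = pipeline_config(),
                                 times_ms = config$class_times_ms) {
  stopifnot(inherits(prep, "preprocessed_recording"))
  fstats <- feature_stats(prep$trials)
  bits <- numeric(length(times_ms)); ntr <- integer(length(times_ms))
  acc <- numeric(length(times_ms))
  cms <- vector("list", length(times_ms))
  for (i in seq_along(times_ms)) {
    cm <- tryCatch(
      classify_windows(prep, times_ms[i], config, fstats = fstats),
      error = function(e) {
        message(sprintf("t = %d ms skipped: %s", times_ms[i], conditionMessage(e)))
        NULL
      })
    if (is.null(cm)) {
      bits[i] <- NA_real_; ntr[i] <- 0L; acc[i] <- NA_real_
    } else {
      bits[i] <- information_content(cm)
      ntr[i] <- sum(cm)
      acc[i] <- attr(cm, "accuracy")
      cms[[i]] <- cm
    }
  }
  if (all(is.na(bits))) stopf("no time point had enough trials and classes")
  structure(list(time_ms = times_ms, bits = bits, n_trials = ntr,
                 accuracy = acc, confusions = cms),
            class = "information_timeline")
}

#' @export
print.information_timeline <- function(x, ...) {
  peak <- which.max(x$bits)
  cat(sprintf("<information_timeline> %d time point(s); peak %.3f bits at %d ms\n",
              length(x$time_ms), x$bits[peak], x$time_ms[peak]))
  invisible(x)
}
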