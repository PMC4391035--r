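test_that("the decoder matches an explicit normal-equations solve", {
  for (seed in 1:5) {
    toy <- linear_toy_trials(noise = 0.5, seed = seed)
    fit <- fit_wiener(toy$trials, outputs = "joints")
    # independent oracle: stack the design and solve X'X beta = X'y directly
    x <- do.call(rbind, lapply(toy$trials$trials, function(tr) {
      t(apply(tr$eeg, 1, function(sl) as.vector(t(sl))))
    }))
    y <- do.call(rbind, lapply(toy$trials$trials, `[[`, "vel"))
    xd <- cbind(1, x)
    beta_oracle <- solve(crossprod(xd), crossprod(xd, y))
    flat <- rbind(fit$intercepts, fit$beta_flat)
    expect_lt(max(abs(flat - beta_oracle)), 1e-8)
    # normal equations satisfied: residuals orthogonal to the design
    resid <- y - xd %*% flat
    expect_lt(max(abs(crossprod(xd, resid))) / nrow(xd), 1e-8)
  }
})

test_that("noise-free generating coefficients are recovered exactly", {
  toy <- linear_toy_trials(noise = 0, seed = 11)
  fit <- fit_wiener(toy$trials, outputs = "joints")
  expect_lt(max(abs(fit$beta_flat[, seq_len(toy$n_out)] - toy$beta)), 1e-8)
  expect_lt(max(abs(fit$intercepts[seq_len(toy$n_out)] - toy$beta0)), 1e-8)
})

test_that("all-zero EEG gives the minimum-norm model: mean intercept, zero slopes", {
  toy <- linear_toy_trials(seed = 2)
  for (i in seq_along(toy$trials$trials)) {
    toy$trials$trials[[i]]$eeg[] <- 0
  }
  expect_warning(fit <- fit_wiener(toy$trials, outputs = "joints"),
                 "minimum-norm")
  expect_true(all(fit$beta_flat == 0))
  y <- do.call(rbind, lapply(toy$trials$trials, `[[`, "vel"))
  expect_equal(unname(fit$intercepts), unname(colMeans(y)), tolerance = 1e-10)
})

test_that("a duplicated channel triggers the rank-deficiency path with finite output", {
  toy <- linear_toy_trials(seed = 3)
  for (i in seq_along(toy$trials$trials)) {
    toy$trials$trials[[i]]$eeg[, 2, ] <- toy$trials$trials[[i]]$eeg[, 1, ]
  }
  expect_warning(fit <- fit_wiener(toy$trials, outputs = "joints"),
                 "minimum-norm")
  expect_true(all(is.finite(fit$beta_flat)))
})

test_that("prediction applies the decoding equation deterministically", {
  toy <- linear_toy_trials(noise = 0, seed = 4)
  fit <- fit_wiener(toy$trials, outputs = "joints")
  pred <- predict(fit, toy$trials)
  obs <- lapply(toy$trials$trials, `[[`, "vel")
  expect_lt(max(abs(pred[[1]] - obs[[1]])), 1e-7)
  # a zero-slope model predicts its constant intercept
  fit0 <- suppressWarnings({
    z <- toy$trials
    for (i in seq_along(z$trials)) z$trials[[i]]$eeg[] <- 0
    fit_wiener(z, outputs = "joints")
  })
  p0 <- predict(fit0, toy$trials)
  expect_true(all(abs(sweep(p0[[1]], 2, fit0$intercepts)) < 1e-10))
  # layout mismatch is an error
  bad <- toy$trials; bad$channel_labels <- rev(bad$channel_labels)
  expect_error(predict(fit, bad), "layout")
})

test_that("training accuracy dominates held-out accuracy on average", {
  delta <- vapply(1:10, function(seed) {
    toy <- linear_toy_trials(n_trials = 8, n_time = 25, noise = 3, seed = seed)
    fit <- fit_wiener(toy$trials, outputs = "joints")
    pred <- predict(fit, toy$trials)
    y <- do.call(rbind, lapply(toy$trials$trials, `[[`, "vel"))
    r_train <- cor(do.call(rbind, pred)[, 1], y[, 1])
    cvres <- suppressMessages(suppressWarnings(
      cross_validate(toy$trials, folds = 4, seed = seed, outputs = "joints",
                     keep_predictions = FALSE)))
    r_train - cvres$median_r[1]
  }, 0)
  expect_gt(mean(delta), 0)
})

test_that("cross-validation partitions trials and is stratified", {
  sim <- cached_small_sim()
  run <- cached_small_run()
  fold_of <- run$result$fold_of
  expect_identical(length(fold_of), length(run$prep$trials$trials))
  expect_true(all(table(fold_of) >= 1))
  # every fold sees every object at least once (10 per object, 8 folds is
  # not enough for all folds; check coverage over pairs of folds instead)
  labs <- run$result$trial_labels
  per_fold <- table(fold_of, labs)
  expect_true(all(rowSums(per_fold) > 0))
  expect_true(all(colSums(per_fold) == 10))
})

test_that("noiseless lagged-linear data cross-validates at r = 1", {
  toy <- linear_toy_trials(n_trials = 10, n_time = 60, noise = 0, seed = 5)
  res <- suppressMessages(suppressWarnings(
    cross_validate(toy$trials, folds = 5, seed = 1, outputs = "joints",
                   keep_predictions = FALSE)))
  expect_gt(min(res$r[, seq_len(toy$n_out)]), 1 - 1e-6)
})

test_that("independent EEG and kinematics decode at chance", {
  # with ~1000 independent test samples per fold the null r has sd ~0.03,
  # so 0.1 is a > 3 sigma bound on the fold median
  set.seed(21)
  eeg_list <- lapply(1:16, function(i) array(rnorm(250 * 4 * 3), dim = c(250, 4, 3)))
  vel_list <- lapply(1:16, function(i) matrix(rnorm(250 * 15), 250))
  ts <- make_trialset(eeg_list, vel_list, joint_labels = default_joint_labels(),
                      labels = rep(object_labels(), length.out = 16))
  res <- suppressMessages(suppressWarnings(
    cross_validate(ts, folds = 4, seed = 2, outputs = "joints",
                   keep_predictions = FALSE)))
  expect_lt(max(abs(res$median_r)), 0.1)
})

test_that("channel ranking follows its formula, order and tie rule", {
  toy <- linear_toy_trials(n_ch = 6, L = 3, n_out = 3, noise = 1, seed = 6)
  fit <- fit_wiener(toy$trials, outputs = "joints")
  fit$coef <- fit$coef[, , 1:3, drop = FALSE]
  # brute-force re-evaluation by naive loops
  rk <- rank_channels(fit)
  n_ch <- dim(fit$coef)[1]; n_lag <- dim(fit$coef)[2]
  r_oracle <- numeric(n_ch)
  for (n in seq_len(n_ch)) {
    acc <- 0
    for (k in seq_len(n_lag)) {
      acc <- acc + sqrt(sum(fit$coef[n, k, 1:3]^2))
    }
    r_oracle[n] <- acc / n_lag
  }
  expect_equal(unname(rk$R_n), r_oracle, tolerance = 1e-12)
  expect_true(all(rk$R_n >= 0))
  expect_identical(sort(rk$order), seq_len(n_ch))

  # single informative channel
  one <- fit
  one$coef[] <- 0
  one$coef[4, , ] <- 1
  rk1 <- rank_channels(one)
  expect_identical(rk1$order[1], 4L)
  expect_true(all(rk1$R_n[-4] == 0))

  # exact ties resolve by channel index
  tie <- fit
  tie$coef[] <- 0.5
  rk2 <- rank_channels(tie)
  expect_identical(rk2$order, seq_len(n_ch))
  expect_error(rank_channels({
    two <- fit; two$coef <- two$coef[, , 1:2, drop = FALSE]; two
  }), "three")
})

test_that("lag contributions normalize to 100 percent", {
  toy <- linear_toy_trials(n_ch = 4, L = 10, n_out = 3, noise = 1, seed = 7)
  fit <- fit_wiener(toy$trials, outputs = "joints")
  fit$coef <- fit$coef[, , 1:3, drop = FALSE]
  lc <- lag_contributions(fit)
  expect_lt(abs(sum(lc$percent) - 100), 1e-6)
  # brute-force oracle
  pct_oracle <- numeric(11)
  denom <- 0
  for (k in 1:11) {
    for (n in 1:4) {
      s <- sqrt(sum(fit$coef[n, k, ]^2))
      pct_oracle[k] <- pct_oracle[k] + s
      denom <- denom + s
    }
  }
  expect_equal(unname(lc$percent), 100 * pct_oracle / denom, tolerance = 1e-10)

  single <- fit; single$coef[] <- 0; single$coef[, 10, ] <- 2  # lag -90 ms
  lcs <- lag_contributions(single)
  expect_equal(unname(lcs$percent[10]), 100)
  expect_true(all(lcs$percent[-10] == 0))

  uniform <- fit; uniform$coef[] <- 0.3
  lcu <- lag_contributions(uniform)
  expect_equal(unname(lcu$percent), rep(100 / 11, 11), tolerance = 1e-10)

  zero <- fit; zero$coef[] <- 0
  expect_error(lag_contributions(zero), "zero")
})

test_that("the double-exponential fit recovers a known peak", {
  n_grid <- 58
  y <- 1 * exp(-0.01 * seq_len(n_grid)) - 1 * exp(-0.3 * seq_len(n_grid))
  # dense-grid argmax oracle on the generating function
  dense <- seq(1, n_grid, by = 1e-3)
  oracle_peak <- round(dense[which.max(exp(-0.01 * dense) - exp(-0.3 * dense))])
  expect_equal(oracle_peak, 12)
  fit <- fit_double_exponential(y, seed = 1)
  expect_true(fit$converged)
  expect_identical(fit$peak_n, 12L)

  # a monotone increasing curve peaks at the last channel
  mono <- 0.8 * (1 - exp(-seq_len(30) / 10))
  fitm <- fit_double_exponential(mono, seed = 2)
  expect_identical(fitm$peak_n, 30L)
})

test_that("accuracy saturates once the informative channels are included", {
  labels16 <- c("C1", "C2", "C3", "C4", "C5", "F1", "F2", "F3", "F4",
                "P1", "P2", "P3", "P4", "O1", "O2", "Oz")
  info <- c("C1", "C2", "C3", "C4", "C5")
  coupling <- list(channels = info, lag_ms = c(40, 60, 80, 90, 100),
                   gains = 0.12 * matrix(c(1, .3, -.2, -.6, .9, .4, .5, -.7,
                                           .8, .2, .9, -.5, -.8, .1, .6),
                                         5, 3, byrow = TRUE))
  spec <- synthetic_spec(n_channels = 16L, montage = labels16, fs = 100,
                         trials_per_object = 8L, informative_channels = info,
                         coupling = coupling, snr = 10)
  sim <- simulate_recording(spec, seed = 31)
  cfg <- pipeline_config(excluded_channels = character(0))
  run <- suppressMessages(suppressWarnings(run_decoding(sim$recording, cfg)))
  curve <- suppressMessages(suppressWarnings(
    accuracy_vs_channels(standardize_trials(run$prep$trials), run$ranking,
                         folds = 8, seed = 1)))
  pc1 <- curve$curve[, "PC1"]
  expect_gt(pc1[5], 0.95 * max(pc1))
  expect_gt(pc1[5] - pc1[1], 0.05)
  expect_true(all(diff(pc1[1:4]) > -0.05))
  expect_true(curve$peak_n["PC1"] >= 3)
})

test_that("correlation significance follows the t transform with Bonferroni", {
  res <- structure(list(r = matrix(c(0, 0.99), 2, 1), n_test = c(100L, 100L)),
                   class = "decoding_result")
  sig <- assess_significance(res, n_comparisons = 1)
  expect_equal(sig$p[1, 1], 1)
  expect_lt(sig$p[2, 1], 1e-10)
  # closed form for r = 0.99, n = 100
  tt <- 0.99 * sqrt(98 / (1 - 0.99^2))
  expect_equal(sig$p[2, 1], 2 * pt(-tt, 98), tolerance = 1e-12)
  sig5 <- assess_significance(res, n_comparisons = 5)
  expect_equal(sig5$p[2, 1], pmin(1, 5 * sig$p[2, 1]), tolerance = 1e-12)
  expect_equal(sig5$p[1, 1], 1)
  res$n_test <- c(2L, 2L)
  expect_error(assess_significance(res), "at least 3")
})
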