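sine_recording <- function(freq, fs = 100, dur = 60, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  recording(matrix(amp * sin(2 * pi * freq * t), 1), fs = fs,
            channel_labels = "Cz")
}

test_that("band-limiting matches the squared Butterworth magnitude response", {
  # forward-backward filtering squares the magnitude response:
  # |H|^2 = 1/(1+(fc/f)^(2o)) (high-pass) * 1/(1+(f/fc)^(2o)) (low-pass)
  gain_at <- function(f) {
    (1 / (1 + (0.3 / f)^8)) * (1 / (1 + (f / 1)^8))
  }
  rec <- bandlimit_eeg(sine_recording(0.6), band = c(0.3, 1), order = 4)
  mid <- rec$eeg[1, 2000:4000]
  obs <- max(abs(mid))
  expect_gte(obs, 0.9)
  expect_lte(obs, 1.0)
  expect_lt(abs(obs - gain_at(0.6)), 0.02)

  rec5 <- bandlimit_eeg(sine_recording(5), band = c(0.3, 1), order = 4)
  expect_lt(max(abs(rec5$eeg[1, 2000:4000])), 0.01)
  expect_lt(max(abs(rec5$eeg[1, 2000:4000])), 5 * sqrt(gain_at(5)))
})

test_that("filtering is zero-phase and maps zero to zero", {
  z <- bandlimit_eeg(recording(matrix(0, 1, 1000), 100, "Cz"), c(0.3, 1), 4)
  expect_true(all(z$eeg == 0))
  rec <- sine_recording(0.6)
  filt <- bandlimit_eeg(rec, c(0.3, 1), 4)
  cc <- ccf(filt$eeg[1, 1500:4500], rec$eeg[1, 1500:4500], lag.max = 50,
            plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges at or above Nyquist are rejected", {
  expect_error(bandlimit_eeg(sine_recording(0.6), band = c(0.3, 60), order = 4),
               "Nyquist")
})

test_that("spatial projection applies exactly and validates dimensions", {
  sim <- cached_small_sim()
  rec <- sim$recording
  ident <- apply_spatial_projection(rec, diag(nrow(rec$eeg)))
  expect_equal(ident$eeg, rec$eeg)
  expect_error(apply_spatial_projection(rec, matrix(0, 3, 2)), "projection")
})

test_that("projecting out the artifact pattern removes frontal artifact variance", {
  spec <- small_spec(trials_per_object = 2L,
                     artifact = list(channels = frontal_channels(),
                                     weights = c(1, 1, 0.8, 0.8),
                                     amplitude = 200))
  sim <- simulate_recording(spec, seed = 12)
  p <- sim$truth$artifact_pattern
  proj <- diag(length(p)) - tcrossprod(p) / sum(p^2)
  cleaned <- apply_spatial_projection(sim$recording, proj)
  v_before <- var(sim$recording$eeg["Fp1", ])
  v_after <- var(cleaned$eeg["Fp1", ])
  expect_lt(v_after, 0.1 * v_before)
})

test_that("channel exclusion drops the peripherals and preserves order", {
  rec <- recording(matrix(rnorm(64 * 50), 64), fs = 100,
                   channel_labels = default_montage())
  out <- exclude_channels(rec, peripheral_channels())
  expect_identical(length(out$channel_labels), 58L)
  expect_identical(out$channel_labels,
                   setdiff(default_montage(), peripheral_channels()))
  expect_identical(exclude_channels(rec, character(0)), rec)
  expect_error(exclude_channels(rec, "XX9"), "unknown channel")
})

test_that("resampling and differentiation give physical rates", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  ramp <- recording(matrix(3 * t, 1), fs, "Cz")
  out <- resample_and_differentiate(ramp, 100)
  expect_equal(ncol(out$eeg), ceiling(length(t) / 10))
  expect_lt(max(abs(out$eeg - 3)), 1e-9)

  const <- resample_and_differentiate(recording(matrix(5, 1, 1000), fs, "Cz"), 100)
  expect_true(all(const$eeg == 0))

  sine <- recording(matrix(2 * sin(2 * pi * 0.5 * t), 1), fs, "Cz")
  dsine <- resample_and_differentiate(sine, 100)
  expect_lt(abs(max(abs(dsine$eeg[1, 100:900])) - 2 * 2 * pi * 0.5) /
              (2 * 2 * pi * 0.5), 0.01)

  expect_error(resample_and_differentiate(ramp, 300), "divide")
})

test_that("the signal-to-error ratio follows its closed form", {
  set.seed(4)
  y <- rnorm(500)
  expect_identical(compute_ser(y, y), Inf)
  v <- var(y)
  noisy0 <- y + sqrt(v) * rnorm(500)
  mse0 <- mean((noisy0 - y)^2)
  expect_equal(compute_ser(y, noisy0), 10 * log10(v / mse0))
  # filtered signal with MSE = Var/100 -> 20 dB
  e <- rnorm(500); e <- e / sqrt(mean(e^2)) * sqrt(v / 100)
  expect_equal(compute_ser(y, y + e), 20, tolerance = 1e-9)
  expect_error(compute_ser(rep(1, 10), rep(1, 10)), "variance")
})

test_that("lag embedding stacks shifted copies with an invalid-history flag", {
  set.seed(6)
  eeg <- matrix(rnorm(3 * 200), 3)
  rec <- recording(eeg, 100, c("a", "b", "c"))
  lt <- lag_embed(rec, L = 10L, step = 1L)
  expect_identical(dim(lt$data), c(200L, 3L, 11L))
  expect_identical(lt$valid_from, 11L)
  expect_identical(lt$lag_ms, seq(0, 100, by = 10))
  for (k in c(0L, 3L, 10L)) {
    expect_equal(lt$data[50, 2, k + 1L], eeg[2, 50 - k])
  }
  cst <- lag_embed(recording(matrix(7, 1, 50), 100, "a"), L = 4L)
  expect_true(all(cst$data == 7))
  l0 <- lag_embed(rec, L = 0L)
  expect_identical(dim(l0$data), c(200L, 3L, 1L))
  expect_equal(l0$data[, , 1], t(eeg), ignore_attr = TRUE)
  expect_error(lag_embed(rec, L = -1L), "non-negative")
})

test_that("segmentation spans the stated margins and rejects short windows", {
  set.seed(8)
  rec <- recording(matrix(rnorm(2000), 1), 100, "Cz",
                   kin = matrix(rnorm(15 * 2000), 15))
  lt <- lag_embed(rec, L = 10L)
  ev <- data.frame(onset = 1000L, offset = 1190L, label = "can")
  ts <- segment_trials(lt, rec, ev, pre_ms = 400, post_ms = 100)
  expect_identical(length(ts$trials), 1L)
  expect_identical(ts$trials[[1]]$n, 241L)
  expect_equal(ts$trials[[1]]$eeg[1, 1, 1], unname(rec$eeg[1, 960]))
  expect_equal(ts$trials[[1]]$eeg[241, 1, 1], unname(rec$eeg[1, 1200]))

  ev2 <- data.frame(onset = c(20L, 1000L), offset = c(120L, 1190L),
                    label = c("cd", "can"))
  expect_warning(ts2 <- segment_trials(lt, rec, ev2, 400, 100), "rejected")
  expect_identical(length(ts2$trials), 1L)
})

test_that("every event becomes a trial when margins fit", {
  sim <- cached_small_sim()
  prep <- cached_small_prep()
  expect_identical(length(prep$trials$trials), nrow(sim$recording$events))
})

test_that("standardization yields unit-variance features and supports fold-safe reuse", {
  set.seed(9)
  eeg_list <- lapply(1:4, function(i) array(rnorm(30 * 2 * 3, mean = 5, sd = 2),
                                            dim = c(30, 2, 3)))
  ts <- make_trialset(eeg_list)
  std <- standardize_trials(ts)
  stacked <- do.call(rbind, lapply(std$trials, function(tr) {
    matrix(tr$eeg, nrow = dim(tr$eeg)[1])
  }))
  mu <- colMeans(stacked)
  sds <- apply(stacked, 2, sd)
  expect_lt(max(abs(mu)), 1e-10)
  expect_true(all(abs(sds - 1) < 1e-6))

  # identical trials stay identical
  ts2 <- make_trialset(list(eeg_list[[1]], eeg_list[[1]]))
  std2 <- standardize_trials(ts2)
  expect_identical(std2$trials[[1]]$eeg, std2$trials[[2]]$eeg)

  # applying stored (training) statistics to the same data reproduces them
  std3 <- standardize_trials(ts, stats = std$stats)
  expect_equal(std3$trials[[1]]$eeg, std$trials[[1]]$eeg)

  # zero-variance features are zeroed with a warning
  flat <- eeg_list
  for (i in seq_along(flat)) flat[[i]][, 1, 1] <- 3
  expect_warning(stdz <- standardize_trials(make_trialset(flat)), "zero-variance")
  expect_true(all(stdz$trials[[1]]$eeg[, 1, 1] == 0))
})

test_that("the composed preprocessing chain is deterministic", {
  sim <- cached_small_sim()
  a <- suppressWarnings(preprocess_recording(sim$recording, pipeline_config()))
  b <- suppressWarnings(preprocess_recording(sim$recording, pipeline_config()))
  expect_identical(a$trials$trials[[5]]$eeg, b$trials$trials[[5]]$eeg)
  expect_identical(a$trials$trials[[5]]$vel, b$trials$trials[[5]]$vel)
})

test_that("processed EEG energy is confined to the analysis band", {
  set.seed(10)
  rec <- recording(matrix(rnorm(2 * 60000), 2), fs = 1000,
                   channel_labels = c("C3", "C4"))
  filt <- bandlimit_eeg(rec, c(0.3, 1), 4)
  down <- resample_and_differentiate(filt, 100)
  x <- down$eeg[1, 500:5500]
  in_band <- band_variance(x, 100, c(0.1, 1.5))
  total <- band_variance(x, 100, c(0, 50))
  expect_lt(1 - in_band / total, 0.01)
})

test_that("the kinematics chain reports per-joint SER", {
  prep <- cached_small_prep()
  expect_length(prep$ser_db, 15L)
  expect_true(all(is.finite(prep$ser_db)))
  expect_named(prep$ser_db, default_joint_labels())
})
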