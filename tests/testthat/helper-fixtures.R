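# Shared fixtures, built in code and cached for the session. The "small"
# session keeps the default montage and coupling but runs at 100 Hz with 10
# trials per object so unit tests stay fast.

.fixture_env <- new.env(parent = emptyenv())

small_spec <- function(...) {
  args <- utils::modifyList(list(fs = 100, trials_per_object = 10L, snr = 10),
                            list(...))
  do.call(synthetic_spec, args)
}

cached_small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_recording(small_spec(), seed = 42)
  }
  .fixture_env$sim
}

cached_small_prep <- function() {
  if (is.null(.fixture_env$prep)) {
    .fixture_env$prep <- suppressWarnings(
      preprocess_recording(cached_small_sim()$recording, pipeline_config()))
  }
  .fixture_env$prep
}

cached_small_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- suppressMessages(suppressWarnings(
      run_decoding(cached_small_sim()$recording, pipeline_config())))
  }
  .fixture_env$run
}

# hand-built trial set for unit tests that do not need the generator:
# `eeg_list` are time x channels x lags arrays, `vel_list` time x joints
make_trialset <- function(eeg_list, vel_list = NULL, labels = NULL,
                          fs = 100, joint_labels = NULL) {
  n <- length(eeg_list)
  labels <- labels %||% rep("can", n)
  if (!is.null(vel_list) && is.null(joint_labels)) {
    joint_labels <- paste0("j", seq_len(ncol(vel_list[[1]])))
  }
  trials <- lapply(seq_len(n), function(i) {
    list(eeg = eeg_list[[i]],
         vel = if (is.null(vel_list)) NULL else vel_list[[i]],
         pc = NULL, label = labels[i],
         onset_in_trial = 1L, n = dim(eeg_list[[i]])[1])
  })
  d <- dim(eeg_list[[1]])
  structure(list(trials = trials,
                 channel_labels = paste0("ch", seq_len(d[2])),
                 joint_labels = joint_labels,
                 L = d[3] - 1L, step = 1L, fs = fs,
                 pre_ms = 0, post_ms = 0,
                 standardized = FALSE, stats = NULL),
            class = "trial_set")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random lag-structured trials where the outputs are an exact linear map of
# the features (for oracle and recovery tests)
linear_toy_trials <- function(n_trials = 6, n_time = 40, n_ch = 5, L = 2,
                              n_out = 2, noise = 0, seed = 1) {
  set.seed(seed)
  beta <- matrix(rnorm(n_ch * (L + 1) * n_out), n_ch * (L + 1), n_out)
  beta0 <- rnorm(n_out)
  eeg_list <- list(); vel_list <- list()
  for (i in seq_len(n_trials)) {
    e <- array(rnorm(n_time * n_ch * (L + 1)), dim = c(n_time, n_ch, L + 1))
    x <- t(apply(e, 1, function(sl) as.vector(t(sl))))
    y <- sweep(x %*% beta, 2, beta0, "+") + noise * matrix(rnorm(n_time * n_out),
                                                           n_time)
    eeg_list[[i]] <- e
    vel_list[[i]] <- cbind(y, matrix(0, n_time, 15 - n_out))
  }
  ts <- make_trialset(eeg_list, vel_list,
                      labels = rep(c("can", "card"), length.out = n_trials),
                      joint_labels = default_joint_labels())
  list(trials = ts, beta = beta, beta0 = beta0, n_out = n_out)
}
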