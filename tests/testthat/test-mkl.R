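retained_montage <- function() setdiff(default_montage(), peripheral_channels())

random_features <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * 58 * 11), n, 58 * 11)
}

test_that("8 regions x 3 widths give 24 positive semidefinite basis kernels", {
  blocks <- getFromNamespace("roi_feature_blocks", "graspdecode")(
    retained_montage(), default_roi_map(), 11L)
  expect_length(blocks, 8L)
  x <- random_features(20)
  kset <- build_kernels(x, blocks, sigmas = c(5, 10, 15))
  expect_length(kset$kernels, 24L)
  for (k in kset$kernels) {
    expect_true(isSymmetric(k, tol = 1e-12))
    ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_equal(unname(diag(k)), rep(1, 20))
  }
})

test_that("identical samples give all-ones kernels with a floored width scale", {
  x <- matrix(1, 5, 4)
  expect_warning(kset <- build_kernels(x, list(A = 1:4), sigmas = c(5, 10)),
                 "zero median")
  for (k in kset$kernels) expect_true(all(k == 1))
})

test_that("cross kernels reproduce the training kernels on the training set", {
  x <- matrix(rnorm(15 * 6), 15, 6)
  kset <- build_kernels(x, list(A = 1:3, B = 4:6), sigmas = c(5, 10))
  cross <- getFromNamespace("kernel_cross", "graspdecode")(kset, x)
  for (m in seq_along(cross)) {
    expect_equal(cross[[m]], kset$kernels[[m]], tolerance = 1e-10)
  }
})

test_that("single-kernel SimpleMKL agrees with a standard SVM", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 2.5), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  kset <- build_kernels(x, list(A = 1:2), sigmas = 1)
  fit <- train_simplemkl(kset, y, cost = 1)
  expect_identical(fit$fits[[1]]$d, 1)
  dec_our <- predict(fit, x)$decision[, 1]
  k <- kset$kernels[[1]]
  ks <- kernlab::ksvm(kernlab::as.kernelMatrix(k), factor(y), C = 1,
                      scaled = FALSE, tol = 1e-9)
  co <- unlist(kernlab::coef(ks))
  dec_ks <- as.numeric(k[, kernlab::SVindex(ks)] %*% co) - kernlab::b(ks)
  s <- sign(cor(dec_our, dec_ks))
  expect_lt(max(abs(dec_our - s * dec_ks)), 1e-6)
})

test_that("the SVM dual solution satisfies the KKT system of its margin set", {
  set.seed(1)
  x <- matrix(rnorm(12), 6, 2)
  y <- rep(c(1, -1), 3)
  k <- exp(-as.matrix(dist(x))^2 / 2)
  # hard-margin regime: no alpha saturates at C, so the KKT equality system
  # over the margin set determines the solution in closed form
  big_c <- 1e6
  sol <- getFromNamespace("solve_svm_dual", "graspdecode")(k, y, big_c)
  expect_true(all(sol$alpha < big_c * (1 - 1e-7)))
  sv <- which(sol$alpha > 1e-7)
  expect_gt(length(sv), 1L)
  q <- (tcrossprod(y) * k)[sv, sv]
  kkt <- rbind(cbind(q, y[sv]), c(y[sv], 0))
  exact <- solve(kkt, c(rep(1, length(sv)), 0))
  expect_lt(max(abs(sol$alpha[sv] - exact[seq_along(sv)])), 1e-4)
  expect_lt(abs(sol$b - exact[length(exact)]), 1e-4)
})

test_that("SimpleMKL keeps the simplex and never increases the objective", {
  set.seed(9)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 12), n, 12)
  x[y == "b", 5:8] <- x[y == "b", 5:8] + 1.5
  kset <- build_kernels(x, list(LF = 1:4, LSM = 5:8, RPO = 9:12),
                        sigmas = c(5, 10, 15))
  fit <- suppressWarnings(train_simplemkl(kset, y, cost = 1))
  b <- fit$fits[[1]]
  expect_lt(abs(sum(b$d) - 1), 1e-6)
  expect_gt(min(b$d), -1e-9)
  expect_true(all(diff(b$obj_trace) <= 1e-8))
  # the informative region should dominate the learned weights
  lsm <- sum(b$d[kset$meta$roi == "LSM"])
  expect_gte(lsm, 0.5)
})

test_that("identical basis kernels leave the uniform weights untouched", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 2), 10, 2))
  y <- rep(c("a", "b"), each = 10)
  kset <- build_kernels(x, list(A = 1:2), sigmas = 1)
  kset$kernels <- rep(kset$kernels, 3)
  kset$meta <- kset$meta[rep(1, 3), ]
  fit <- train_simplemkl(kset, y, cost = 1)
  expect_equal(fit$fits[[1]]$d, rep(1 / 3, 3), tolerance = 1e-9)
  expect_gt(mean(predict(fit, x)$class == y), 0.8)
})

test_that("linearly separable classes are fit perfectly", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2), matrix(rnorm(40, 3, 0.3), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  fit <- suppressWarnings(
    train_simplemkl(build_kernels(x, list(A = 1:2), sigmas = c(5, 10, 15)), y))
  expect_identical(mean(predict(fit, x)$class == y), 1)
})

test_that("information content matches the analytic and brute-force values", {
  diag5 <- diag(10, 5)
  expect_equal(information_content(diag5), log2(5), tolerance = 1e-12)
  indep <- outer(c(10, 20, 30, 25, 15), c(4, 8, 12, 10, 6))
  expect_lt(information_content(indep), 1e-12)
  cm2 <- matrix(c(30, 10, 10, 30), 2, 2, byrow = TRUE)
  # brute force over the four cells
  total <- sum(cm2); i_oracle <- 0
  for (i in 1:2) for (j in 1:2) {
    pij <- cm2[i, j] / total
    i_oracle <- i_oracle + pij * log2(pij / (sum(cm2[i, ]) / total *
                                               sum(cm2[, j]) / total))
  }
  expect_equal(information_content(cm2), i_oracle, tolerance = 1e-12)
  # invariant under simultaneous row/column permutation
  p <- c(2, 1)
  expect_equal(information_content(cm2[p, p]), information_content(cm2))
  expect_error(information_content(matrix(0, 2, 2)), "empty")
  expect_lte(information_content(diag5), log2(5))
})

test_that("window classification pools a labelled confusion matrix across folds", {
  prep <- cached_small_prep()
  cfg <- pipeline_config(mkl_max_iter = 5L, mkl_tol = 1e-2)
  cm <- suppressWarnings(classify_windows(prep, time_ms = 250, config = cfg))
  expect_identical(dim(unclass(cm)), c(5L, 5L))
  expect_identical(sort(rownames(cm)), sort(object_labels()))
  # row sums equal the per-class trial counts at this time point
  expect_true(all(rowSums(cm) == 10L))
  expect_gt(attr(cm, "accuracy"), 0.2)
})

test_that("permuted labels classify at the five-class chance level", {
  prep <- cached_small_prep()
  cfg <- pipeline_config(mkl_max_iter = 2L, mkl_tol = 1e-2, cv_folds = 4L)
  acc <- vapply(1:10, function(rep_i) {
    cfg$seed <- rep_i
    cm <- suppressWarnings(classify_windows(prep, time_ms = 250, config = cfg,
                                            permute_labels = TRUE))
    attr(cm, "accuracy")
  }, 0)
  expect_lt(abs(mean(acc) - 0.2), 0.06)
})

test_that("information peaks only where class differences are injected", {
  prep <- cached_small_prep()
  cfg <- pipeline_config(mkl_max_iter = 5L, mkl_tol = 1e-2)
  tl <- suppressWarnings(
    information_timeline(prep, cfg,
                         times_ms = c(-1000, -500, 0, 250, 500, 1000, 3000)))
  expect_identical(length(tl$bits), 7L)
  peak_t <- tl$time_ms[which.max(tl$bits)]
  expect_true(peak_t >= 0 && peak_t <= 1000)
  # pre-movement rest carries no class information beyond small-sample bias
  bias <- (5 - 1)^2 / (2 * 50 * log(2))
  expect_lt(tl$bits[tl$time_ms == -1000], bias + 0.15)
  expect_gt(max(tl$bits, na.rm = TRUE), 2 * tl$bits[tl$time_ms == -1000])
})
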