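# Scaling, ANOVA filter, kernels, the MKL SVM and the two-tiered LOO.

test_that("z-scaling uses training statistics with the n-1 convention", {
  zs <- zscale_fit_apply(cbind(c(1, 2, 3)), cbind(c(2)))
  expect_equal(zs$train[, 1], c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(zs$scale[[1]], 1)           # sd of 1,2,3 with n-1
  tr <- matrix(rnorm(20), 10, 2)
  zs2 <- zscale_fit_apply(tr, tr)
  expect_equal(zs2$train, zs2$test)
  zs3 <- zscale_fit_apply(cbind(rep(5, 4), rnorm(4)))
  expect_equal(unname(zs3$train[, 1]), rep(0, 4))
  expect_match(run_log(zs3), "constant")
})

test_that("the per-ROI ANOVA filter keeps the right columns and counts", {
  set.seed(1)
  n <- 20
  labels <- rep(c("patient", "control"), each = 10)
  X <- matrix(rnorm(n * 250), n, 250)
  X[labels == "patient", 241] <- X[labels == "patient", 241] + 10  # separator
  blocks <- c(rep(1L, 240), rep(2L, 10))
  mask <- anova_select(X, labels, fraction = 0.10, block_index = blocks)
  expect_identical(sum(mask[1:240]), 24L)      # ceiling(0.10 * 240)
  expect_identical(sum(mask[241:250]), 1L)     # ceiling(0.10 * 10)
  expect_true(mask[241])                       # the separating column
  ## F-statistic oracle on a few columns
  f_oracle <- sapply(1:5, function(j)
    summary(stats::aov(X[, j] ~ labels))[[1]]$`F value`[1])
  g1 <- labels == "patient"
  f_mine <- sapply(1:5, function(j) {
    m1 <- mean(X[g1, j]); m2 <- mean(X[!g1, j]); gm <- mean(X[, j])
    ssb <- 10 * (m1 - gm)^2 + 10 * (m2 - gm)^2
    ssw <- sum((X[g1, j] - m1)^2) + sum((X[!g1, j] - m2)^2)
    ssb / (ssw / (n - 2))
  })
  expect_equal(f_mine, f_oracle, tolerance = 1e-8)
})

test_that("unit normalization produces unit rows and is idempotent", {
  expect_equal(unit_normalize(rbind(c(3, 4)))[1, ], c(0.6, 0.8))
  set.seed(2)
  X <- matrix(rnorm(30), 5, 6)
  u <- unit_normalize(X)
  expect_equal(unname(rowSums(u^2)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unit_normalize(u), u, tolerance = 1e-12)
  z <- unit_normalize(rbind(c(0, 0), c(1, 1)))
  expect_equal(z[1, ], c(0, 0))
  expect_match(run_log(z), "zero")
})

test_that("RBF kernels match brute-force pairwise distances", {
  set.seed(3)
  X <- matrix(rnorm(4 * 6), 4, 6)
  blocks <- rep(1:2, each = 3)
  ks <- compute_roi_kernels(X, blocks, gamma = 0.7)
  for (m in 1:2) {
    xb <- X[, blocks == m]
    oracle <- outer(1:4, 1:4, Vectorize(function(i, j)
      exp(-0.7 * sum((xb[i, ] - xb[j, ])^2))))
    expect_equal(ks$kernels[[m]], oracle, tolerance = 1e-12)
    expect_equal(diag(ks$kernels[[m]]), rep(1, 4))
  }
  ## duplicated subjects and the small-gamma limit
  X2 <- rbind(X[1, ], X[1, ], X[3:4, ])
  k2 <- compute_roi_kernels(X2, blocks, gamma = 1)$kernels[[1]]
  expect_equal(k2[1, 2], 1)
  k0 <- compute_roi_kernels(X, blocks, gamma = 1e-12)$kernels[[1]]
  expect_true(all(abs(k0 - 1) < 1e-9))
  expect_error(compute_roi_kernels(X, blocks, gamma = 0), "positive")
})

test_that("single-kernel MKL equals an independent reference SVM", {
  skip_if_not_installed("kernlab")
  set.seed(4)
  n <- 16
  X <- matrix(rnorm(n * 2), n, 2); X[1:8, ] <- X[1:8, ] + 1.2
  labels <- rep(c("patient", "control"), each = 8)
  y <- as_svm_labels(labels)
  K <- exp(-0.4 * as.matrix(dist(X))^2)
  C <- 1.5
  fit <- fit_mkl_svm(list(K), labels, C = C)
  expect_equal(fit$weights, 1)
  ## reference 1: kernlab QP (ipop) solution of the same dual
  Q <- (y %o% y) * K
  qp <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(as.numeric(y), 1),
                      b = 0, l = rep(0, n), u = rep(C, n), r = 0, sigf = 12)
  a_ref <- kernlab::primal(qp)
  free <- which(a_ref > 1e-6 & a_ref < C - 1e-6)
  b_ref <- mean(y[free] - (K %*% (a_ref * y))[free])
  dec_ref <- drop(K %*% (a_ref * y)) + b_ref
  dec_fit <- predict_mkl(fit, list(K))
  expect_lt(max(abs(dec_fit - dec_ref)), 1e-6)
  ## reference 2: kernlab SMO (ksvm) coefficients
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(labels), C = C,
                     type = "C-svc", tol = 1e-9)
  a_k <- rep(0, n); a_k[kernlab::SVindex(m)] <- abs(unlist(kernlab::alpha(m)))
  expect_lt(max(abs(fit$alpha - a_k)), 1e-6)
})

test_that("the MKL SVM separates a separable toy and satisfies its invariants", {
  set.seed(5)
  n <- 20
  X <- matrix(rnorm(n * 4), n, 4); X[1:10, ] <- X[1:10, ] + 3
  labels <- rep(c("patient", "control"), each = 10)
  y <- as_svm_labels(labels)
  blocks <- rep(1:2, each = 2)
  ks <- compute_roi_kernels(unit_normalize(X), blocks, gamma = 1)
  fit <- fit_mkl_svm(ks, labels, C = 10)
  dec <- predict_mkl(fit, ks$kernels)
  expect_identical(sign(dec), as.numeric(y))          # training accuracy 1
  ## weights on the simplex
  expect_true(all(fit$weights >= 0))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  ## sum decomposition: sum_m S_m = ||w||^2 on the combined kernel
  Kc <- Reduce(`+`, Map(`*`, fit$weights, ks$kernels))
  ay <- fit$alpha * y
  expect_equal(sum(fit$S), drop(crossprod(ay, Kc %*% ay)), tolerance = 1e-6)
  ## KKT residual of the SVM solution below 1e-6
  G <- drop(((y %o% y) * Kc) %*% fit$alpha) - 1
  up <- (y == 1 & fit$alpha < fit$C - 1e-9) | (y == -1 & fit$alpha > 1e-9)
  lo <- (y == 1 & fit$alpha > 1e-9) | (y == -1 & fit$alpha < fit$C - 1e-9)
  expect_lt(max(-y[up] * G[up]) - min(-y[lo] * G[lo]), 1e-6)
})

test_that("weight learning favors the informative kernel across seeds", {
  w_inf <- numeric(20); first <- logical(20); mono <- logical(20)
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 40
    Xi <- matrix(rnorm(n * 4), n, 4); Xi[1:20, ] <- Xi[1:20, ] + 1.5
    Xn <- matrix(rnorm(n * 4), n, 4)
    labels <- rep(c("patient", "control"), each = 20)
    Ki <- exp(-0.25 * as.matrix(dist(Xi))^2)
    Kn <- exp(-0.25 * as.matrix(dist(Xn))^2)
    fit <- fit_mkl_svm(list(Ki, Kn), labels, C = 1)
    w_inf[s] <- fit$weights[1]
    mono[s] <- all(diff(fit$objective_path) <= 1e-8 * (1 + abs(fit$objective_path[-1])))
    first[s] <- rank_kernels_rck(list(Ki, Kn), labels, C = 1)$ranking[1] == 1
  }
  expect_gt(median(w_inf), 0.5)
  expect_gte(mean(first), 0.8)
  expect_true(all(mono))   # objective non-increasing per iteration
})

test_that("kernel elimination uses the documented tie-break and singleton path", {
  set.seed(6)
  K <- exp(-0.3 * as.matrix(dist(matrix(rnorm(24), 12, 2)))^2)
  labels <- rep(c("patient", "control"), each = 6)
  rk <- rank_kernels_rck(list(K, K, K), labels, C = 1)
  expect_identical(rk$ranking, 1:3)  # identical kernels: higher index out first
  rk1 <- rank_kernels_rck(structure(list(kernels = list(K), roi_ids = 7L,
                                         gamma = 1), class = "kernel_set"),
                          labels, C = 1)
  expect_identical(rk1$roi_ids, 7L)
})

test_that("uniform-weight mode matches a plain averaged-kernel SVM", {
  set.seed(7)
  n <- 14
  X <- matrix(rnorm(n * 4), n, 4); X[1:7, ] <- X[1:7, ] + 2
  labels <- rep(c("patient", "control"), each = 7)
  blocks <- rep(1:2, each = 2)
  ks <- compute_roi_kernels(X, blocks, gamma = 0.5)
  fit_u <- fit_mkl_svm(ks, labels, C = 2, weight_mode = "uniform")
  expect_equal(fit_u$weights, rep(0.5, 2))
  ref <- fit_mkl_svm(list(Reduce(`+`, ks$kernels) / 2), labels, C = 2)
  expect_equal(fit_u$alpha, ref$alpha, tolerance = 1e-8)
})

test_that("the two-tiered LOO is exact on separable data and leak-free on noise", {
  sep <- separable_features(n = 20, shift = 6, seed = 8)
  cv <- nested_loo_evaluate(sep$ft, sep$labels, C_grid = c(1, 10),
                            gamma_grid = c(0.5, 2))
  expect_equal(cv$accuracy, 1.0)
  expect_equal(cv$sensitivity, 1.0)
  expect_equal(cv$specificity, 1.0)
  ## every fold trained without its held-out subject
  for (f in cv$folds) expect_false(f$subject %in% f$train_idx)
  ## randomized labels: mean accuracy within the binomial band of 0.5
  accs <- sapply(1:10, function(r) {
    set.seed(700 + r)
    X <- matrix(rnorm(24 * 60), 24, 60)
    ft <- make_feature_table(X, rep(1:3, each = 20))
    nested_loo_evaluate(ft, sample(rep(c("patient", "control"), each = 12)),
                        C_grid = c(1, 10), gamma_grid = 1)$accuracy
  })
  n_pred <- 10 * 24
  band <- 1.96 * sqrt(0.25 / n_pred)
  expect_gt(mean(accs), 0.5 - band - 0.05)
  expect_lt(mean(accs), 0.5 + band + 0.05)
})

test_that("a minimal cohort produces the expected fold structure", {
  sep <- separable_features(n = 6, p_per_block = 4, n_blocks = 2,
                            shift = 4, seed = 9)
  cv <- nested_loo_evaluate(sep$ft, sep$labels, C_grid = 1, gamma_grid = 1)
  expect_length(cv$folds, 6L)
  for (f in cv$folds) {
    expect_length(f$train_idx, 5L)
    ## inner LOO over 5 training subjects: accuracy on a 1/5 grid
    expect_equal(f$inner_accuracy * 5, round(f$inner_accuracy * 5),
                 tolerance = 1e-9)
  }
  expect_error(nested_loo_evaluate(sep$ft, sep$labels, C_grid = numeric(0),
                                   gamma_grid = 1), "non-empty")
})

test_that("hyperparameter ties resolve toward smaller C then smaller gamma", {
  sep <- separable_features(n = 12, shift = 8, seed = 10)
  cv <- nested_loo_evaluate(sep$ft, sep$labels, C_grid = c(0.5, 8),
                            gamma_grid = 0.25)
  ## trivially separable: both C values are perfect, tie goes to the smaller
  expect_equal(cv$inner_accuracy, 1.0)
  expect_true(all(cv$selected_C == 0.5))
  cv2 <- nested_loo_evaluate(sep$ft, sep$labels, C_grid = 8,
                             gamma_grid = c(0.25, 0.5))
  expect_equal(cv2$inner_accuracy, 1.0)
  expect_true(all(cv2$selected_gamma == 0.25))
})
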