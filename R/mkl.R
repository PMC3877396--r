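# Multiple-kernel-learning classifier over per-ROI kernels --------------------
#
# Features are grouped by atlas ROI; each group gets an RBF kernel and the
# kernels are combined with learned nonnegative weights on the probability
# simplex (alternating optimization between the SVM dual for fixed weights
# and a multiplicative weight update proportional to each kernel's margin
# contribution).  Recursive kernel elimination ranks ROIs; a two-tiered
# leave-one-out cross-validation selects (C, gamma) and the peak ROI counts
# and predicts each held-out subject by majority vote over the peak region.

#' Convert group labels to +/-1 SVM labels
#'
#' @param labels character/factor labels; `positive` (default `"patient"` if
#'   present, else the first sorted level) is coded +1.
#' @param positive the positive-class label.
#' @return integer vector of +1/-1 with attribute `positive`.
#' @export
as_svm_labels <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("need exactly two classes", call. = FALSE)
  positive <- positive %||% if ("patient" %in% u) "patient" else u[1]
  structure(ifelse(labels == positive, 1L, -1L), positive = positive)
}

#' z-scale features by training statistics
#'
#' Columns are centered and scaled by training mean and standard deviation
#' (denominator n - 1); the same training statistics scale the test rows.
#' Zero-variance training columns are scaled by 1 (logged).
#'
#' @param train,test numeric matrices with matching columns (`test` may be
#'   `NULL`).
#' @return list with `train`, `test`, `center`, `scale`; degenerate columns
#'   noted in [run_log()].
#' @export
zscale_fit_apply <- function(train, test = NULL) {
  assert_matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  degenerate <- scl == 0
  scl[degenerate] <- 1
  out <- list(train = sweep(sweep(train, 2, ctr), 2, scl, "/"),
              test = if (!is.null(test))
                sweep(sweep(test, 2, ctr), 2, scl, "/"),
              center = ctr, scale = scl)
  if (any(degenerate))
    out <- log_note(out, sprintf("%d constant training column(s) left unscaled",
                                 sum(degenerate)))
  out
}

#' Per-ROI ANOVA feature filter
#'
#' Within every ROI block, keeps the `ceiling(fraction * block size)` columns
#' with the largest one-way (two-group) F statistic computed on training rows
#' only; ties broken toward the lower column index. The ceiling rule
#' guarantees no ROI is emptied.
#'
#' @param train training feature matrix.
#' @param labels training group labels (two classes).
#' @param fraction fraction of columns retained per block (default 0.10).
#' @param block_index ROI id per column.
#' @return logical column mask.
#' @export
anova_select <- function(train, labels, fraction = 0.10, block_index) {
  assert_matrix(train)
  y <- as_svm_labels(labels)
  if (length(block_index) != ncol(train))
    stop("block_index length must match feature count", call. = FALSE)
  g1 <- y == 1L; g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2); n <- n1 + n2
  m1 <- colMeans(train[g1, , drop = FALSE])
  m2 <- colMeans(train[g2, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums(sweep(train[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(train[g2, , drop = FALSE], 2, m2)^2)
  f_stat <- ifelse(ssw > 0, ssb / (ssw / (n - 2)), ifelse(ssb > 0, Inf, 0))
  mask <- logical(ncol(train))
  for (b in unique(block_index)) {
    cols <- which(block_index == b)
    if (!length(cols)) stop("empty ROI block", call. = FALSE)
    keep_n <- ceiling(fraction * length(cols))
    ord <- cols[order(-f_stat[cols], cols)]
    mask[ord[seq_len(keep_n)]] <- TRUE
  }
  mask
}

#' Normalize each subject's feature vector to unit Euclidean length
#'
#' @param x subjects x features matrix.
#' @return matrix with unit-norm rows; all-zero rows left unchanged (logged).
#' @export
unit_normalize <- function(x) {
  assert_matrix(x)
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  out <- x / nrm
  if (any(zero))
    out <- log_note(out, sprintf("%d all-zero feature vector(s) left at zero",
                                 sum(zero)))
  out
}

#' Per-ROI RBF kernel set
#'
#' Kernel `m` has entries `exp(-gamma * ||x_i - x_j||^2)` over the columns of
#' ROI `m` of the (scaled, selected, unit-normalized) feature matrix.
#'
#' @param x subjects x features matrix.
#' @param block_index ROI id per column.
#' @param gamma RBF width (> 0).
#' @return `kernel_set`: list with `kernels` (list of n x n matrices),
#'   `roi_ids`, `gamma`.
#' @export
compute_roi_kernels <- function(x, block_index, gamma) {
  assert_matrix(x)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  roi_ids <- unique(block_index)
  kernels <- lapply(roi_ids, function(b) {
    xb <- x[, block_index == b, drop = FALSE]
    sq <- rowSums(xb^2)
    d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(xb), 0)
    exp(-gamma * d2)
  })
  structure(list(kernels = kernels, roi_ids = roi_ids, gamma = gamma),
            class = "kernel_set")
}

#' Fit the MKL SVM on a kernel set
#'
#' Alternates between solving the soft-margin SVM dual on the weighted kernel
#' sum and a multiplicative simplex update `d_m <- d_m * sqrt(S_m)`
#' (renormalized), where `S_m` is kernel `m`'s contribution to the squared
#' weight norm. A damped step keeps the fixed-weight dual value non-increasing
#' across iterations. With a single kernel the result is a standard RBF SVM.
#'
#' @param kernel_set a [compute_roi_kernels()] result (or plain list of
#'   kernel matrices).
#' @param labels two-class labels.
#' @param C soft-margin parameter.
#' @param weight_mode `"learned"` (default) or `"uniform"` (fixed equal
#'   weights; ablation mode).
#' @param tol_d convergence tolerance on `max |delta d|` (default 1e-4).
#' @param max_outer maximum alternating iterations (default 100).
#' @return `mkl_model`: simplex `weights`, dual `alpha`, bias `b`, per-kernel
#'   contributions `S`, `objective_path`, `support` indices, `converged`.
#' @export
fit_mkl_svm <- function(kernel_set, labels, C = 1,
                        weight_mode = c("learned", "uniform"),
                        tol_d = 1e-4, max_outer = 100L) {
  weight_mode <- match.arg(weight_mode)
  kernels <- if (inherits(kernel_set, "kernel_set")) kernel_set$kernels
             else kernel_set
  y <- as_svm_labels(labels)
  if (min(table(y)) < 2L) stop("need at least 2 subjects per class", call. = FALSE)
  if (weight_mode == "uniform") {
    M <- length(kernels)
    K <- Reduce(`+`, kernels) / M
    s <- .smo_svm(K, y, C)
    ay <- s$alpha * y
    fit <- list(weights = rep(1 / M, M), alpha = s$alpha, b = s$b,
                S = vapply(kernels, function(Km)
                  (1 / M) * drop(crossprod(ay, Km %*% ay)), numeric(1)),
                objective_path = s$objective, converged = TRUE)
  } else {
    fit <- .mkl_fit(kernels, y, C, tol_d = tol_d, max_outer = max_outer)
    if (!fit$converged)
      warning("MKL alternating optimization did not converge; returning last iterate",
              call. = FALSE)
  }
  structure(list(weights = as.numeric(fit$weights),
                 alpha = as.numeric(fit$alpha), b = fit$b,
                 S = as.numeric(fit$S),
                 objective_path = as.numeric(fit$objective_path),
                 support = which(fit$alpha > 1e-8),
                 C = C,
                 gamma = if (inherits(kernel_set, "kernel_set"))
                   kernel_set$gamma,
                 roi_ids = if (inherits(kernel_set, "kernel_set"))
                   kernel_set$roi_ids,
                 y = y, converged = fit$converged,
                 weight_mode = weight_mode),
            class = "mkl_model")
}

#' Decision values of an MKL model on new kernel columns
#'
#' @param model an `mkl_model`.
#' @param kernel_cols list (per kernel, same order as at fit time) of
#'   n_train x n_new cross-kernel matrices.
#' @return numeric decision values (positive = positive class).
#' @export
predict_mkl <- function(model, kernel_cols) {
  K <- Reduce(`+`, Map(`*`, model$weights, kernel_cols))
  drop(crossprod(K, model$alpha * model$y)) + model$b
}

#' Rank ROIs by recursive kernel elimination
#'
#' Repeatedly fits the MKL SVM and removes the kernel with the smallest
#' contribution to the squared weight norm (ties: higher ROI index first);
#' the ranking is the reverse elimination order (first = most informative).
#'
#' @inheritParams fit_mkl_svm
#' @return `rck_ranking`: list with `roi_ids` (ranked), `ranking` (kernel
#'   positions), `elimination_scores`.
#' @export
rank_kernels_rck <- function(kernel_set, labels, C = 1, ...) {
  kernels <- if (inherits(kernel_set, "kernel_set")) kernel_set$kernels
             else kernel_set
  y <- as_svm_labels(labels)
  if (length(kernels) == 1L) {
    res <- list(ranking = 1L, elimination_scores = numeric(0))
  } else {
    res <- .rck_rank(kernels, y, C, ...)
  }
  roi_ids <- if (inherits(kernel_set, "kernel_set")) kernel_set$roi_ids
             else seq_along(kernels)
  structure(list(roi_ids = roi_ids[res$ranking],
                 ranking = as.integer(res$ranking),
                 elimination_scores = as.numeric(res$elimination_scores)),
            class = "rck_ranking")
}

## per-outer-fold preparation: scale by training stats, ANOVA filter on
## training labels, unit-normalize, and build per-gamma ROI kernels over
## (train..., test) with the test subject last
prepare_fold_kernels <- function(X, block_index, train_idx, test_idx, labels,
                                 fraction, gamma_grid) {
  zs <- zscale_fit_apply(X[train_idx, , drop = FALSE],
                         X[test_idx, , drop = FALSE])
  mask <- anova_select(zs$train, labels[train_idx], fraction, block_index)
  Xall <- unit_normalize(rbind(zs$train[, mask, drop = FALSE],
                               zs$test[, mask, drop = FALSE]))
  blocks <- block_index[mask]
  ks <- lapply(gamma_grid, function(g) compute_roi_kernels(Xall, blocks, g))
  list(kernel_sets = ks, blocks = blocks, mask = mask,
       n_train = length(train_idx))
}

#' Two-tiered leave-one-out evaluation of the MKL classifier
#'
#' Outer LOO over subjects estimates test performance. Inside each outer
#' training set the features are z-scaled, ANOVA-filtered per ROI and
#' unit-normalized (all statistics from outer-training subjects only), ROIs
#' are ranked once by recursive kernel elimination at reference
#' hyperparameters (median C, median gamma of the grids), and an inner LOO
#' over the (C, gamma) grid and ROI counts along the ranking selects the
#' hyperparameters (ties toward smaller C, then smaller gamma) and the peak
#' region: all ROI counts attaining the inner-accuracy maximum. The held-out
#' subject is predicted by every peak-count classifier and a majority vote
#' (ties: the class with the larger mean decision value).
#'
#' @param x a `feature_table` (cohort-wide PCA features) or a `cohort_maps`
#'   object, in which case the per-ROI PCA is refitted inside every outer
#'   training set (`fold_safe` feature mode).
#' @param labels two-class labels, one per subject.
#' @param C_grid,gamma_grid hyperparameter grids (defaults `2^seq(-5, 15, 2)`
#'   and `2^seq(-15, 3, 2)`).
#' @param fraction ANOVA retention fraction per ROI (default 0.10).
#' @param k PCA scores per block when `x` is a `cohort_maps`.
#' @param weight_mode passed to [fit_mkl_svm()].
#' @return `cv_result`: per-fold records (prediction, truth, selected C and
#'   gamma, peak counts, inner accuracy, training indices) plus aggregate
#'   accuracy, sensitivity, specificity, inner-CV accuracy, and mean and sd
#'   of the ROI count at peak discrimination.
#' @export
nested_loo_evaluate <- function(x, labels,
                                C_grid = 2^seq(-5, 15, 2),
                                gamma_grid = 2^seq(-15, 3, 2),
                                fraction = 0.10, k = 10L,
                                weight_mode = c("learned", "uniform")) {
  weight_mode <- match.arg(weight_mode)
  if (!length(C_grid) || !length(gamma_grid))
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  fold_safe <- inherits(x, "cohort_maps")
  n <- if (fold_safe) length(x$maps) else nrow(x$matrix)
  if (n < 6L) stop("need at least 6 subjects for the two-tiered LOO", call. = FALSE)
  labels <- as.character(labels)
  y <- as_svm_labels(labels)
  positive <- attr(y, "positive")
  C_grid <- sort(C_grid)
  gamma_grid <- sort(gamma_grid)
  c_ref <- stats::median(C_grid)
  g_ref_idx <- ceiling(length(gamma_grid) / 2)

  folds <- vector("list", n)
  for (i in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), i)
    if (fold_safe) {
      ft <- pca_reduce_maps(x, k = k, mode = "fold_safe", train_idx = train_idx)
      X <- ft$matrix; block_index <- ft$block_index
    } else {
      X <- x$matrix; block_index <- x$block_index
    }
    prep <- prepare_fold_kernels(X, block_index, train_idx, i, labels,
                                 fraction, gamma_grid)
    n_tr <- prep$n_train
    tr <- seq_len(n_tr)
    train_kernels <- lapply(prep$kernel_sets, function(ks)
      lapply(ks$kernels, function(K) K[tr, tr, drop = FALSE]))
    y_tr <- y[train_idx]

    ranking <- rank_kernels_rck(
      structure(list(kernels = train_kernels[[g_ref_idx]],
                     roi_ids = unique(prep$blocks), gamma = gamma_grid[g_ref_idx]),
                class = "kernel_set"),
      labels[train_idx], C = c_ref)

    acc <- .inner_loo(train_kernels, y_tr, C_grid, ranking$ranking)
    best <- max(acc)
    ## ties toward smaller C, then smaller gamma (grids sorted ascending)
    hit <- which(acc == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2], hit[, 3]), , drop = FALSE]
    ci <- hit[1, 1]; gi <- hit[1, 2]
    peak_counts <- sort(unique(hit[hit[, 1] == ci & hit[, 2] == gi, 3]))

    dec <- .predict_counts(prep$kernel_sets[[gi]]$kernels, y_tr,
                           ranking$ranking, C_grid[ci])$decision
    dec_peak <- dec[peak_counts]
    votes <- sign(dec_peak)
    vote_sum <- sum(votes)
    pred <- if (vote_sum != 0) sign(vote_sum) else
      if (mean(dec_peak) >= 0) 1 else -1

    folds[[i]] <- list(subject = i, true = y[i], predicted = as.integer(pred),
                       C = C_grid[ci], gamma = gamma_grid[gi],
                       peak_counts = as.integer(peak_counts),
                       inner_accuracy = best,
                       train_idx = train_idx)
  }

  truth <- vapply(folds, `[[`, integer(1), "true")
  pred <- vapply(folds, `[[`, integer(1), "predicted")
  peak_mean_per_fold <- vapply(folds, function(f) mean(f$peak_counts), numeric(1))
  structure(list(
    folds = folds,
    positive = positive,
    accuracy = mean(pred == truth),
    sensitivity = mean(pred[truth == 1] == 1),
    specificity = mean(pred[truth == -1] == -1),
    inner_accuracy = mean(vapply(folds, `[[`, numeric(1), "inner_accuracy")),
    peak_rois_mean = mean(peak_mean_per_fold),
    peak_rois_sd = sd(peak_mean_per_fold),
    selected_C = vapply(folds, `[[`, numeric(1), "C"),
    selected_gamma = vapply(folds, `[[`, numeric(1), "gamma")),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("nested LOO: accuracy %.1f%% (inner CV %.1f%%), sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$accuracy, 100 * x$inner_accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  cat(sprintf("ROIs at peak discrimination: %.1f +/- %.1f\n",
              x$peak_rois_mean, x$peak_rois_sd))
  invisible(x)
}
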