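# Balanced label-permutation null for classifier significance -----------------
#
# The permuted label sets preserve the original class counts; the null run
# uses two deliberate simplifications relative to the full procedure: the
# soft-margin parameter (and RBF width) selected on the real labels is kept
# fixed, and instead of optimizing the ROI count, the accuracy is taken as
# the maximum over ROI counts along the ranking — a positively biased
# (conservative) null.

#' Generate balanced permuted label sets
#'
#' Each of the `B` label vectors is an independent uniformly random shuffle
#' of the original labels, so the number of positive and negative examples
#' is preserved exactly; the `B` sets are drawn with replacement (duplicate
#' vectors are allowed).
#'
#' @param labels two-class label vector.
#' @param B number of permuted sets (default 1000).
#' @param seed integer seed.
#' @return a length-`B` list of label vectors.
#' @export
balanced_permutations <- function(labels, B = 1000L, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("need two classes", call. = FALSE)
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(B), function(b) sample(labels))
}

#' Permutation null distribution of the classifier accuracy
#'
#' For every permuted labeling, runs the outer LOO with the supplied fixed
#' `(C, gamma)`: per fold, training features are z-scaled, ANOVA-filtered
#' with the permuted training labels and unit-normalized, ROIs ranked by
#' recursive kernel elimination, and the held-out subject predicted at every
#' ROI count; the null statistic is the accuracy maximized over ROI counts.
#' The p-value uses the add-one estimator `(1 + r) / (B + 1)` and can never
#' be zero.
#'
#' @param features a `feature_table`.
#' @param labels true labels.
#' @param perms list of permuted label vectors from [balanced_permutations()].
#' @param C,gamma hyperparameters fixed from the real-label run.
#' @param observed the observed (real-label) accuracy.
#' @param fraction ANOVA retention fraction per ROI.
#' @param weight_mode passed to the MKL fit.
#' @return `null_distribution`: list with `values` (B max-accuracies),
#'   `observed`, `p_value`, `B`.
#' @export
null_distribution <- function(features, labels, perms, C, gamma, observed,
                              fraction = 0.10,
                              weight_mode = c("learned", "uniform")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(inherits(features, "feature_table"))
  labels <- as.character(labels)
  n <- nrow(features$matrix)
  B <- length(perms)

  ## per-fold z-scaling is label-independent: precompute once
  scaled_folds <- lapply(seq_len(n), function(i) {
    train_idx <- setdiff(seq_len(n), i)
    zs <- zscale_fit_apply(features$matrix[train_idx, , drop = FALSE],
                           features$matrix[i, , drop = FALSE])
    list(train = zs$train, test = zs$test, train_idx = train_idx)
  })

  eval_labels <- function(lab) {
    y <- as_svm_labels(lab)
    M <- length(unique(features$block_index))
    correct <- matrix(0, n, M)
    for (i in seq_len(n)) {
      sf <- scaled_folds[[i]]
      mask <- anova_select(sf$train, lab[sf$train_idx], fraction,
                           features$block_index)
      Xall <- unit_normalize(rbind(sf$train[, mask, drop = FALSE],
                                   sf$test[, mask, drop = FALSE]))
      blocks <- features$block_index[mask]
      ks <- compute_roi_kernels(Xall, blocks, gamma)
      n_tr <- n - 1L
      train_kernels <- lapply(ks$kernels, function(K)
        K[seq_len(n_tr), seq_len(n_tr), drop = FALSE])
      rk <- rank_kernels_rck(
        structure(list(kernels = train_kernels, roi_ids = ks$roi_ids,
                       gamma = gamma), class = "kernel_set"),
        lab[sf$train_idx], C = C)
      dec <- .predict_counts(ks$kernels, y[sf$train_idx], rk$ranking, C)$decision
      pred <- ifelse(dec >= 0, 1L, -1L)
      correct[i, seq_along(pred)] <- pred == y[i]
    }
    max(colMeans(correct))
  }

  values <- vapply(perms, eval_labels, numeric(1))
  p <- (1 + sum(values >= observed)) / (B + 1)
  structure(list(values = values, observed = observed, p_value = p, B = B),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("permutation null: observed accuracy %.3f, B = %d, p = %.4g\n",
              x$observed, x$B, x$p_value))
  invisible(x)
}
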