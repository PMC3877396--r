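# Seed-based correlation maps and per-ROI PCA features ------------------------
#
# Each motor seed's mean time course is correlated with every grey-matter
# voxel, giving one correlation map per seed (24 maps for the default seed
# set: 12 per hemisphere covering M1, supplementary motor area, basal
# ganglia, thalamus and cerebellar subdivisions).  Maps are reduced across
# subjects by anatomical ROI with PCA to a fixed number of scores per ROI
# (deliberately not scaled to ROI size), and the reduced maps concatenated
# into the classifier's feature table.

#' Default motor seed table for an atlas
#'
#' One seed per motor region, excluding the paracentral lobule: for the
#' default 116-region synthetic atlas this yields 12 seeds per hemisphere
#' (M1, SMA, caudate, putamen, pallidum, thalamus and six cerebellar
#' subdivisions), 24 in total.
#'
#' @param atlas atlas table from [cohort_atlas()].
#' @return data.frame with columns `seed_id`, `hemisphere`, `regions`
#'   (comma-separated atlas labels averaged into the seed course).
#' @export
default_seed_table <- function(atlas) {
  motor <- atlas[atlas$role %in% c("cortical_motor", "subcortical_motor") &
                   !grepl("^paracentral", atlas$label), , drop = FALSE]
  data.frame(seed_id = paste0("seed_", motor$label),
             hemisphere = motor$hemisphere,
             regions = motor$label,
             stringsAsFactors = FALSE)
}

#' Seed-based correlation maps for one subject
#'
#' The seed time course is the mean of its member regions' (preprocessed)
#' series; the map value is the Pearson correlation between that course and
#' each voxel series. Zero-variance voxels get correlation 0, with a logged
#' count.
#'
#' @param subject a preprocessed `subject_data`.
#' @param seeds seed table (see [default_seed_table()]).
#' @return `seed_map_set`: list with `maps` (seeds x voxels matrix in
#'   `[-1, 1]`), `seed_ids`, `subject_id`, `group`.
#' @export
compute_seed_maps <- function(subject, seeds) {
  stopifnot(inherits(subject, "subject_data"))
  if (is.null(subject$preprocessed) || !isTRUE(subject$preprocessed))
    warning("subject does not appear to be preprocessed", call. = FALSE)
  labels <- colnames(subject$region_series)
  courses <- vapply(seq_len(nrow(seeds)), function(i) {
    members <- trimws(strsplit(seeds$regions[i], ",")[[1]])
    missing <- setdiff(members, labels)
    if (length(missing))
      stop(sprintf("seed '%s' references unknown region label(s): %s",
                   seeds$seed_id[i], paste(missing, collapse = ", ")),
           call. = FALSE)
    rowMeans(subject$region_series[, members, drop = FALSE])
  }, numeric(nrow(subject$region_series)))
  vox <- subject$voxel_series
  vox_sd <- apply(vox, 2, sd)
  zero_var <- vox_sd == 0
  maps <- t(suppressWarnings(cor(vox, courses)))
  if (any(zero_var)) maps[, zero_var] <- 0
  rownames(maps) <- seeds$seed_id
  out <- structure(list(maps = maps, seed_ids = seeds$seed_id,
                        subject_id = subject$subject_id, group = subject$group,
                        voxel_to_region = subject$voxel_to_region),
                   class = "seed_map_set")
  if (any(zero_var))
    out <- log_note(out, sprintf("%d zero-variance voxel(s) set to correlation 0",
                                 sum(zero_var)))
  out
}

#' Seed maps for a whole cohort
#' @param cohort a preprocessed `mkl_cohort`.
#' @param seeds seed table; defaults to [default_seed_table()] of the
#'   cohort's atlas.
#' @return list of class `cohort_maps`: per-subject `seed_map_set`s plus the
#'   atlas and seed table.
#' @export
cohort_seed_maps <- function(cohort, seeds = NULL) {
  seeds <- seeds %||% default_seed_table(cohort$atlas)
  structure(list(maps = lapply(cohort$subjects, compute_seed_maps, seeds = seeds),
                 atlas = cohort$atlas, seeds = seeds,
                 labels = cohort_labels(cohort)),
            class = "cohort_maps")
}

## PCA of one (seed, ROI) block: subjects x voxels, centered per voxel on the
## training rows; scores = projections on the top-k training principal
## directions, sign fixed so each direction's largest-magnitude loading is
## positive; missing directions (rank or voxel shortfall) padded with zeros.
pca_block_scores <- function(X, k, train_idx) {
  ctr <- colMeans(X[train_idx, , drop = FALSE])
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc[train_idx, , drop = FALSE], nu = 0)
  keep <- which(sv$d > max(sv$d[1], 1e-12) * 1e-10)
  keep <- head(keep, k)
  scores <- matrix(0, nrow(X), k)
  if (length(keep)) {
    V <- sv$v[, keep, drop = FALSE]
    flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
    V <- sweep(V, 2, flip, `*`)
    scores[, seq_along(keep)] <- Xc %*% V
  }
  list(scores = scores, padded = k - length(keep))
}

#' Reduce seed maps to the per-ROI PCA feature table
#'
#' For every (seed map, ROI) pair the subjects-by-voxels block is centered
#' per voxel and projected onto its top-`k` principal directions, keeping
#' `k` scores per subject regardless of ROI size (blocks with fewer
#' directions are zero-padded, logged). In `"cohort"` mode the PCA is fitted
#' across all subjects (the reference procedure, which leaks held-out
#' information into features when later cross-validated); in `"fold_safe"`
#' mode it is fitted on `train_idx` only and applied to everyone.
#'
#' @param cmaps a `cohort_maps` from [cohort_seed_maps()].
#' @param k scores kept per (seed, ROI) block (default 10).
#' @param mode `"cohort"` (cohort-wide fit) or `"fold_safe"`.
#' @param train_idx subject indices used to fit the PCA in `"fold_safe"`
#'   mode.
#' @return a `feature_table`: list with `matrix` (subjects x
#'   `n_regions * n_seeds * k`), `block_index` (ROI id per column),
#'   `roi_ids`, `k`, `mode`.
#' @export
pca_reduce_maps <- function(cmaps, k = 10L, mode = c("cohort", "fold_safe"),
                            train_idx = NULL) {
  mode <- match.arg(mode)
  n_sub <- length(cmaps$maps)
  if (n_sub < 2L) stop("need at least 2 subjects for across-subject PCA",
                       call. = FALSE)
  if (mode == "cohort") {
    train_idx <- seq_len(n_sub)
    message("PCA mode 'cohort': components fitted across all subjects; ",
            "held-out information leaks into features under cross-validation. ",
            "Use mode 'fold_safe' for leakage-free estimates.")
  } else if (is.null(train_idx)) {
    stop("fold_safe mode requires train_idx", call. = FALSE)
  }
  if (length(train_idx) < k + 1L)
    warning(sprintf("only %d training subjects for k = %d scores; trailing scores will be zero",
                    length(train_idx), k), call. = FALSE)
  v2r <- cmaps$maps[[1]]$voxel_to_region
  seed_ids <- cmaps$seeds$seed_id
  roi_ids <- sort(unique(v2r$region_id))
  per_seed <- lapply(seq_along(seed_ids), function(s) {
    M <- t(vapply(cmaps$maps, function(m) m$maps[s, ], numeric(nrow(v2r))))
    blocks <- lapply(roi_ids, function(r) {
      pca_block_scores(M[, v2r$region_id == r, drop = FALSE], k, train_idx)
    })
    mat <- do.call(cbind, lapply(blocks, `[[`, "scores"))
    colnames(mat) <- paste0("roi", rep(roi_ids, each = k), "_",
                            seed_ids[s], "_pc", rep(seq_len(k), length(roi_ids)))
    structure(list(matrix = mat, block_index = rep(roi_ids, each = k),
                   roi_ids = roi_ids, k = k, mode = mode,
                   subject_ids = vapply(cmaps$maps, `[[`, character(1),
                                        "subject_id"),
                   padded = sum(vapply(blocks, `[[`, numeric(1), "padded"))),
              class = "feature_table")
  })
  ft <- assemble_feature_table(per_seed)
  padded <- sum(vapply(per_seed, `[[`, numeric(1), "padded"))
  if (padded > 0)
    ft <- log_note(ft, sprintf("%d zero-padded PCA score column(s) (ROI smaller than k or rank-deficient)",
                               padded))
  ft
}

#' Concatenate per-map feature tables
#'
#' @param tables list of `feature_table`s over the same subjects in the same
#'   order.
#' @return a single `feature_table` with columns concatenated and a combined
#'   block index.
#' @export
assemble_feature_table <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ids <- tables[[1]]$subject_ids
  for (tb in tables[-1])
    if (!identical(tb$subject_ids, ids))
      stop("subject ordering differs across map tables", call. = FALSE)
  structure(list(matrix = do.call(cbind, lapply(tables, `[[`, "matrix")),
                 block_index = unlist(lapply(tables, `[[`, "block_index")),
                 roi_ids = tables[[1]]$roi_ids,
                 k = tables[[1]]$k, mode = tables[[1]]$mode,
                 subject_ids = ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature table: %d subjects x %d features (%d ROI blocks, k = %d, mode = %s)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$block_index)),
              x$k, x$mode))
  invisible(x)
}

#' Serialize / load a feature table
#' @param ft a `feature_table`.
#' @param path basename; writes `<path>.csv` (matrix) and `<path>.json`
#'   (block index and metadata).
#' @return invisibly, the paths written; `read_feature_table` returns the
#'   `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  data.table::fwrite(data.table::as.data.table(ft$matrix),
                     paste0(path, ".csv"))
  jsonlite::write_json(list(block_index = ft$block_index, roi_ids = ft$roi_ids,
                            k = ft$k, mode = ft$mode,
                            subject_ids = ft$subject_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, c(".csv", ".json")))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(matrix = as.matrix(data.table::fread(paste0(path, ".csv"))),
                 block_index = meta$block_index, roi_ids = meta$roi_ids,
                 k = meta$k, mode = meta$mode, subject_ids = meta$subject_ids),
            class = "feature_table")
}
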