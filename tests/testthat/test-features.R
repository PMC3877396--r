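# Seed maps and per-ROI PCA reduction.

test_that("seed correlation maps match the closed-form Pearson oracle", {
  T_n <- 10
  region <- cbind(r1 = rnorm(T_n), r2 = rnorm(T_n))
  vox <- cbind(region[, 1], rnorm(T_n), rnorm(T_n))
  colnames(vox) <- paste0("v", 1:3)
  s <- make_subject(region, vox,
                    data.frame(voxel = 1:3, region_id = c(1L, 1L, 2L)))
  seeds <- data.frame(seed_id = "seed_r1", hemisphere = "L", regions = "r1")
  sm <- compute_seed_maps(s, seeds)
  expect_equal(unname(sm$maps[1, 1]), 1.0, tolerance = 1e-12)
  ## hand-computed Pearson for a toy pair
  x <- region[, 1]; y <- vox[, 2]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(sm$maps[1, 2]), r_hand, tolerance = 1e-10)
  expect_error(compute_seed_maps(s, data.frame(seed_id = "bad",
                                               hemisphere = "L",
                                               regions = "nope")),
               "unknown region")
})

test_that("zero-variance voxels get correlation zero with a logged count", {
  T_n <- 12
  region <- cbind(r1 = rnorm(T_n))
  vox <- cbind(v1 = rnorm(T_n), v2 = rep(1, T_n))
  s <- make_subject(region, vox,
                    data.frame(voxel = 1:2, region_id = c(1L, 1L)))
  seeds <- data.frame(seed_id = "s", hemisphere = "L", regions = "r1")
  sm <- compute_seed_maps(s, seeds)
  expect_identical(unname(sm$maps[1, 2]), 0)
  expect_match(run_log(sm), "zero-variance")
})

test_that("default seed set and feature dimensions follow the atlas arithmetic", {
  spec <- cohort_spec(n_patients = 6, n_controls = 6, voxels_per_region = 10,
                      T_vol = 60, seed = 2)
  atlas <- cohort_atlas(spec)
  seeds <- default_seed_table(atlas)
  expect_identical(nrow(seeds), 24L)
  expect_identical(sum(seeds$hemisphere == "L"), 12L)

  co <- preprocess_cohort(generate_cohort(spec))
  cm <- cohort_seed_maps(co)
  expect_length(cm$maps, 12L)
  expect_identical(dim(cm$maps[[1]]$maps), c(24L, 1160L))

  ft <- suppressMessages(suppressWarnings(pca_reduce_maps(cm, k = 10)))
  expect_identical(ncol(ft$matrix), 116L * 24L * 10L)  # 27,840
  blocks <- table(ft$block_index)
  expect_length(blocks, 116L)
  expect_true(all(blocks == 240L))
})

test_that("PCA block scores match the eigendecomposition oracle up to sign", {
  set.seed(3)
  X <- matrix(rnorm(8 * 5), 8, 5)
  sc <- mklconn:::pca_block_scores(X, k = 4, train_idx = 1:8)$scores
  Xc <- scale(X, scale = FALSE)
  eg <- eigen(crossprod(Xc))
  oracle <- Xc %*% eg$vectors[, 1:4]
  for (j in 1:4) {
    d <- min(max(abs(sc[, j] - oracle[, j])), max(abs(sc[, j] + oracle[, j])))
    expect_lt(d, 1e-8)
  }
  ## scores are uncorrelated across subjects
  cc <- crossprod(scale(sc, scale = FALSE))
  off <- abs(cc[upper.tri(cc)]) / max(diag(cc))
  expect_lt(max(off), 1e-6)
})

test_that("rank-1 data loads a single component; small ROIs are zero-padded", {
  set.seed(4)
  u <- rnorm(9); v <- rnorm(6)
  X <- outer(u, v)
  sc <- mklconn:::pca_block_scores(X, k = 4, train_idx = 1:9)$scores
  vars <- apply(sc, 2, var)
  expect_gt(vars[1] / sum(vars), 0.999)
  expect_lt(max(abs(sc[, 2:4])), 1e-6)
  ## ROI with fewer voxels than k: trailing scores zero
  sc2 <- mklconn:::pca_block_scores(matrix(rnorm(18), 9, 2), k = 5,
                                    train_idx = 1:9)
  expect_equal(sc2$padded, 3)
  expect_true(all(sc2$scores[, 3:5] == 0))
})

test_that("feature tables concatenate consistently and round-trip to disk", {
  a <- make_feature_table(matrix(rnorm(40), 4, 10), rep(1:2, each = 5))
  b <- make_feature_table(matrix(rnorm(40), 4, 10), rep(1:2, each = 5))
  ab <- assemble_feature_table(list(a, b))
  expect_identical(ncol(ab$matrix), 20L)
  expect_identical(ab$block_index, c(a$block_index, b$block_index))
  bad <- b; bad$subject_ids <- rev(b$subject_ids)
  expect_error(assemble_feature_table(list(a, bad)), "ordering")

  path <- tempfile("ft")
  write_feature_table(ab, path)
  back <- read_feature_table(path)
  expect_equal(unname(back$matrix), unname(ab$matrix))
  expect_identical(back$block_index, ab$block_index)
  unlink(paste0(path, c(".csv", ".json")))
})

test_that("fold-safe PCA never uses the held-out subject", {
  spec <- tiny_spec(seed = 8, n_patients = 3, n_controls = 3,
                    n_regions = 6L, n_motor_cortical = 2L,
                    n_motor_subcortical = 2L)
  co <- preprocess_cohort(generate_cohort(spec))
  cm <- cohort_seed_maps(co)
  ft1 <- pca_reduce_maps(cm, k = 2, mode = "fold_safe", train_idx = 1:5)
  ## corrupt the held-out subject's maps: training-subject scores unchanged
  cm2 <- cm
  cm2$maps[[6]]$maps <- cm2$maps[[6]]$maps * 10
  ft2 <- pca_reduce_maps(cm2, k = 2, mode = "fold_safe", train_idx = 1:5)
  expect_equal(ft1$matrix[1:5, ], ft2$matrix[1:5, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ft1$matrix[6, ], ft2$matrix[6, ])))
  ## cohort-wide mode is affected (the documented leakage)
  ft3 <- suppressMessages(pca_reduce_maps(cm, k = 2))
  ft4 <- suppressMessages(pca_reduce_maps(cm2, k = 2))
  expect_false(isTRUE(all.equal(ft3$matrix[1:5, ], ft4$matrix[1:5, ])))
})
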