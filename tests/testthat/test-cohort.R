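# Synthetic cohort generator: covariance construction, sampling consistency,
# serialization round trips.

test_that("group covariances encode the three connectivity effects", {
  spec0 <- cohort_spec(n_patients = 4, n_controls = 4, n_regions = 12,
                       n_motor_cortical = 4, n_motor_subcortical = 4,
                       delta1 = 0, delta2 = 0, delta3 = 0)
  expect_identical(make_group_covariance(spec0, "patient"),
                   make_group_covariance(spec0, "control"))

  spec <- cohort_spec(n_patients = 4, n_controls = 4, n_regions = 12,
                      n_motor_cortical = 4, n_motor_subcortical = 4,
                      base_coupling = 0.3, delta1 = 0.2, delta2 = 0.1,
                      delta3 = 0.05)
  ctl <- make_group_covariance(spec, "control")
  pat <- make_group_covariance(spec, "patient")
  sub <- 5:8; cort <- 1:4; non <- 9:12
  off <- function(m, idx) mean(m[idx, idx][upper.tri(m[idx, idx])])
  expect_equal(off(pat, sub) - off(ctl, sub), 0.2, tolerance = 1e-12)
  expect_equal(mean(pat[sub, cort] - ctl[sub, cort]), -0.1, tolerance = 1e-12)
  expect_equal(mean(pat[c(cort, sub), non] - ctl[c(cort, sub), non]), -0.05,
               tolerance = 1e-12)
  expect_equal(unname(diag(pat)), rep(1, 12))
})

test_that("implied covariances are positive definite (eigenvalue oracle)", {
  for (seed in 1:3) {
    spec <- cohort_spec(n_patients = 4, n_controls = 4,
                        n_regions = c(12, 30, 116)[seed],
                        n_motor_cortical = 4,
                        n_motor_subcortical = c(4, 6, 20)[seed],
                        delta1 = 0.3, delta2 = 0.15, delta3 = 0.1)
    for (g in c("patient", "control")) {
      ev <- eigen(make_group_covariance(spec, g), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
  expect_error(cohort_spec(base_coupling = 0.4, delta2 = 1.5),
               "outside")
})

test_that("default spec yields 70 subjects with 180 x 116 region series", {
  spec <- cohort_spec()
  co <- generate_cohort(spec)
  expect_length(co$subjects, 70L)
  expect_identical(dim(co$subjects[[1]]$region_series), c(180L, 116L))
  expect_identical(dim(co$subjects[[1]]$voxel_series), c(180L, 1160L))
  expect_identical(table(cohort_labels(co))[["patient"]], 40L)
  expect_identical(table(cohort_labels(co))[["control"]], 30L)
})

test_that("noiseless limit reproduces region series at every voxel", {
  spec <- tiny_spec(voxel_noise_sd = 0, motion_amp = 0, csf_wm_amp = 0)
  co <- generate_cohort(spec)
  s <- co$subjects[[1]]
  expected <- s$region_series[, s$voxel_to_region$region_id]
  expect_equal(unname(s$voxel_series), unname(expected), tolerance = 1e-12)
})

test_that("empirical within-block correlation matches the specification at large T", {
  spec <- cohort_spec(n_patients = 2, n_controls = 2, n_regions = 12,
                      n_motor_cortical = 4, n_motor_subcortical = 4,
                      voxels_per_region = 1, T_vol = 2000,
                      base_coupling = 0.4, delta1 = 0, delta2 = 0, delta3 = 0,
                      motion_amp = 0, csf_wm_amp = 0, voxel_noise_sd = 0,
                      seed = 7)
  co <- generate_cohort(spec)
  ## non-motor block: regions 9-12
  r <- sapply(co$subjects, function(s) cor(s$region_series[, 9],
                                           s$region_series[, 10]))
  expect_true(all(abs(r - 0.4) < 0.05))
})

test_that("generation is deterministic given spec and seed", {
  a <- generate_cohort(tiny_spec(seed = 42))
  b <- generate_cohort(tiny_spec(seed = 42))
  expect_identical(a, b)
  c2 <- generate_cohort(tiny_spec(seed = 43))
  expect_false(identical(a$subjects[[1]]$region_series,
                         c2$subjects[[1]]$region_series))
})

test_that("groups are statistically indistinguishable at zero deltas", {
  spec <- desk_cohort_spec("null", seed = 5, n_patients = 10, n_controls = 10,
                           voxels_per_region = 1, motion_amp = 0,
                           csf_wm_amp = 0, voxel_noise_sd = 0)
  co <- generate_cohort(spec)
  ## Fisher-z two-sample test per region pair
  z <- t(sapply(co$subjects, function(s) {
    cm <- cor(s$region_series)
    atanh(cm[upper.tri(cm)])
  }))
  pat <- cohort_labels(co) == "patient"
  p <- apply(z, 2, function(v) stats::t.test(v[pat], v[!pat])$p.value)
  ## 45 tests at level 0.05: expect about 2 rejections; 8 would be extreme
  expect_lt(sum(p < 0.05), 8)
})

test_that("injected nuisance is recoverable by regression", {
  co <- generate_cohort(tiny_spec(seed = 3))
  s <- co$subjects[[1]]
  nuis <- build_nuisance_matrix(s$motion, s$csf, s$wm)
  res <- regress_out(s$region_series, nuis)
  v_before <- apply(s$region_series, 2, var)
  v_after <- apply(res, 2, var)
  expect_true(all(v_after <= v_before + 1e-12))
  expect_lt(mean(v_after / v_before), 1)
})

test_that("cohort write/read round trip is exact and sidecars validated", {
  dir <- tempfile("cohort")
  co <- generate_cohort(tiny_spec(seed = 9, n_patients = 2, n_controls = 2))
  co$subjects <- co$subjects[1:3]
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (i in 1:3) {
    expect_equal(back$subjects[[i]]$region_series,
                 co$subjects[[i]]$region_series)
    expect_equal(back$subjects[[i]]$voxel_series,
                 co$subjects[[i]]$voxel_series)
    expect_equal(back$subjects[[i]]$csf, unname(co$subjects[[i]]$csf))
    expect_identical(back$subjects[[i]]$group, co$subjects[[i]]$group)
  }
  ## malformed sidecar: invalid group value
  side <- file.path(dir, "sub-001.json")
  j <- jsonlite::read_json(side, simplifyVector = TRUE)
  j$group <- "zombie"
  jsonlite::write_json(j, side, auto_unbox = TRUE, digits = NA)
  expect_error(read_cohort(dir), "group 'zombie'")
  file.remove(side)
  expect_error(read_cohort(dir), "missing sidecar")
  unlink(dir, recursive = TRUE)
})

test_that("NIfTI export re-parcellates back to the region means", {
  skip_if_not_installed("RNifti")
  spec <- tiny_spec(seed = 13, n_patients = 2, n_controls = 2,
                    voxels_per_region = 6, voxel_noise_sd = 0.2)
  co <- generate_cohort(spec)
  dir <- tempfile("nii")
  paths <- export_cohort_nifti(co, dir)
  rec <- reparcellate_nifti(file.path(dir, "sub-001_bold.nii"),
                            file.path(dir, "atlas.nii"))
  s <- co$subjects[[1]]
  v2r <- s$voxel_to_region
  truth <- vapply(sort(unique(v2r$region_id)), function(r)
    rowMeans(s$voxel_series[, v2r$region_id == r, drop = FALSE]),
    numeric(nrow(s$voxel_series)))
  expect_equal(unname(rec), unname(truth), tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("short acquisitions are rejected", {
  expect_error(cohort_spec(T_vol = 10), "too short")
})
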