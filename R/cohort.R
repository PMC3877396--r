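# Synthetic two-group resting-state cohorts -----------------------------------
#
# Region-level BOLD-like series are drawn from group-dependent covariance
# matrices built on a motor/non-motor block layout: a cortical motor block,
# a subcortical motor block (basal ganglia, thalamus, cerebellum) and
# non-motor blocks.  Patients differ from controls by three effects:
#   delta1  increased coupling within the subcortical motor block,
#   delta2  reduced subcortical-to-cortical motor coupling,
#   delta3  reduced motor-to-non-motor coupling.
# Voxel series replicate their region signal plus independent noise; motion,
# CSF and white-matter confounds are injected additively with per-region
# random loadings so that nuisance regression is a meaningful operation.

#' Construct a synthetic cohort specification
#'
#' All parameters of the cohort generator in one validated object. Defaults
#' describe a 40-patient / 30-control cohort of 180 volumes at TR = 3 s over
#' a 116-region parcellation.
#'
#' @param n_patients,n_controls group sizes (each at least 2).
#' @param n_regions number of atlas regions.
#' @param n_motor_cortical,n_motor_subcortical sizes of the cortical and
#'   subcortical motor blocks (regions `1..n_motor_cortical` are cortical
#'   motor, the next `n_motor_subcortical` subcortical motor, the rest
#'   non-motor; named labels come from the atlas lookup table, see
#'   [cohort_atlas()]).
#' @param voxels_per_region voxels simulated per region.
#' @param T_vol number of volumes (time points); must be at least 20.
#' @param TR repetition time in seconds.
#' @param base_coupling within-block correlation in `[0, 1)`; between-block
#'   baseline coupling is `base_coupling / 2`.
#' @param delta1 patient increase of within-subcortical-motor coupling.
#' @param delta2 patient decrease of subcortical-to-cortical motor coupling.
#' @param delta3 patient decrease of motor-to-non-motor coupling.
#' @param nonmotor_block_size size of the non-motor coupling blocks.
#' @param ar_coef AR(1) temporal smoothing coefficient in `[0, 1)`.
#' @param motion_amp,voxel_noise_sd,csf_wm_amp nonnegative nuisance /
#'   noise scales (in units of the unit-variance region signal).
#' @param seed integer seed; identical spec + seed gives identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 40L, n_controls = 30L,
                        n_regions = 116L,
                        n_motor_cortical = 6L, n_motor_subcortical = 20L,
                        voxels_per_region = 10L,
                        T_vol = 180L, TR = 3.0,
                        base_coupling = 0.35,
                        delta1 = 0.15, delta2 = 0.12, delta3 = 0.10,
                        nonmotor_block_size = 4L,
                        ar_coef = 0.3,
                        motion_amp = 0.8, voxel_noise_sd = 0.5,
                        csf_wm_amp = 0.8,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               n_controls = as.integer(n_controls),
               n_regions = as.integer(n_regions),
               n_motor_cortical = as.integer(n_motor_cortical),
               n_motor_subcortical = as.integer(n_motor_subcortical),
               voxels_per_region = as.integer(voxels_per_region),
               T_vol = as.integer(T_vol), TR = TR,
               base_coupling = base_coupling,
               delta1 = delta1, delta2 = delta2, delta3 = delta3,
               nonmotor_block_size = as.integer(nonmotor_block_size),
               ar_coef = ar_coef,
               motion_amp = motion_amp, voxel_noise_sd = voxel_noise_sd,
               csf_wm_amp = csf_wm_amp,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_patients < 2L || n_controls < 2L)
      stop("group sizes must be at least 2", call. = FALSE)
    if (n_motor_cortical + n_motor_subcortical > n_regions)
      stop("motor blocks exceed n_regions", call. = FALSE)
    if (T_vol < 20L)
      stop("T_vol < 20: series too short to filter and correlate meaningfully",
           call. = FALSE)
    if (base_coupling < 0 || base_coupling >= 1)
      stop("base_coupling must lie in [0, 1)", call. = FALSE)
    if (ar_coef < 0 || ar_coef >= 1)
      stop("ar_coef must lie in [0, 1)", call. = FALSE)
    if (min(motion_amp, voxel_noise_sd, csf_wm_amp) < 0)
      stop("noise amplitudes must be nonnegative", call. = FALSE)
  })
  ## implied correlations must stay inside (-1, 1)
  implied <- c(spec$base_coupling + spec$delta1,
               spec$base_coupling / 2 - spec$delta2,
               spec$base_coupling / 2 - spec$delta3)
  if (any(abs(implied) >= 1))
    stop("deltas push implied correlations outside (-1, 1)", call. = FALSE)
  ## both group covariances must be positive definite (ridge repair is
  ## attempted inside make_group_covariance and logged; rejection surfaces here)
  for (g in c("control", "patient")) make_group_covariance(spec, g)
  spec
}

#' Atlas lookup table for a synthetic cohort
#'
#' Maps region indices to motor-system roles and left/right labels. Cortical
#' motor regions are named after the precentral gyrus (M1), supplementary
#' motor area and paracentral lobule; subcortical motor regions after the
#' basal ganglia, thalamus and cerebellar subdivisions.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `region_id`, `label`, `role`
#'   (`cortical_motor`, `subcortical_motor`, `non_motor`) and `hemisphere`.
#' @export
cohort_atlas <- function(spec) {
  cort <- c("precentral_L", "precentral_R",
            "supp_motor_area_L", "supp_motor_area_R",
            "paracentral_L", "paracentral_R")
  sub_base <- as.vector(t(outer(c("caudate", "putamen", "pallidum", "thalamus"),
                                c("L", "R"), paste, sep = "_")))
  cereb <- as.vector(t(outer(paste0("cerebellum_", 1:20),
                             c("L", "R"), paste, sep = "_")))
  sub <- c(sub_base, cereb)
  nmc <- spec$n_motor_cortical; nms <- spec$n_motor_subcortical
  lab_c <- if (nmc <= length(cort)) cort[seq_len(nmc)] else
    c(cort, paste0("cortical_motor_", seq_len(nmc - length(cort))))
  lab_s <- sub[seq_len(nms)]
  n_non <- spec$n_regions - nmc - nms
  lab_n <- if (n_non > 0)
    paste0("nonmotor_", sprintf("%03d", seq_len(n_non)),
           c("_L", "_R")[1 + (seq_len(n_non) + 1) %% 2]) else character(0)
  labels <- c(lab_c, lab_s, lab_n)
  data.frame(region_id = seq_len(spec$n_regions),
             label = labels,
             role = rep(c("cortical_motor", "subcortical_motor", "non_motor"),
                        c(nmc, nms, n_non)),
             hemisphere = ifelse(grepl("_L$", labels), "L",
                                 ifelse(grepl("_R$", labels), "R", "M")),
             stringsAsFactors = FALSE)
}

## Region block ids: cortical motor = 1, subcortical motor = 2, non-motor
## chunks = 3, 4, ... of size nonmotor_block_size.
region_blocks <- function(spec) {
  nmc <- spec$n_motor_cortical; nms <- spec$n_motor_subcortical
  n_non <- spec$n_regions - nmc - nms
  c(rep(1L, nmc), rep(2L, nms),
    if (n_non > 0) 2L + ((seq_len(n_non) - 1L) %/% spec$nonmotor_block_size + 1L))
}

#' Group-level region covariance matrix
#'
#' Controls get a block-structured correlation matrix: `base_coupling` inside
#' each block, `base_coupling / 2` between blocks, unit diagonal. Patients
#' additionally get `+delta1` inside the subcortical motor block, `-delta2`
#' on subcortical x cortical motor entries and `-delta3` on motor x non-motor
#' entries. Positive definiteness is checked; a near-singular matrix is
#' ridge-repaired (logged) and a spec needing more than a 10% ridge rejected.
#'
#' @param spec a [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @return a symmetric positive-definite `n_regions x n_regions` matrix with
#'   unit diagonal; any ridge repair is recorded in [run_log()].
#' @export
make_group_covariance <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  n <- spec$n_regions
  blocks <- region_blocks(spec)
  same_block <- outer(blocks, blocks, "==")
  sigma <- matrix(spec$base_coupling / 2, n, n)
  sigma[same_block] <- spec$base_coupling
  if (group == "patient") {
    role <- rep(c("cm", "sm", "nm"),
                c(spec$n_motor_cortical, spec$n_motor_subcortical,
                  n - spec$n_motor_cortical - spec$n_motor_subcortical))
    sm <- role == "sm"; cm <- role == "cm"; motor <- role != "nm"
    sigma[sm, sm] <- sigma[sm, sm] + spec$delta1
    sigma[sm, cm] <- sigma[sm, cm] - spec$delta2
    sigma[cm, sm] <- sigma[cm, sm] - spec$delta2
    sigma[motor, !motor] <- sigma[motor, !motor] - spec$delta3
    sigma[!motor, motor] <- sigma[!motor, motor] - spec$delta3
  }
  diag(sigma) <- 1
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  note <- NULL
  if (ev <= 1e-10) {
    r <- abs(ev) + 1e-6
    if (r > 0.1)
      stop(sprintf("%s covariance not positive definite (min eigenvalue %.3g); spec rejected",
                   group, ev), call. = FALSE)
    sigma <- (sigma + r * diag(n)) / (1 + r)
    note <- sprintf("ridge repair %.3g applied to %s covariance", r, group)
  }
  if (!is.null(note)) sigma <- log_note(sigma, note)
  sigma
}

## moving-average smoother used for confound series (window w, edges shrink)
smooth_ma <- function(x, w = 5L) {
  as.vector(stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE))
}

scale_to_sd <- function(x, s) {
  x <- x - mean(x)
  v <- sd(x)
  if (v > 0) x * (s / v) else x
}

#' Generate a synthetic two-group cohort
#'
#' Region series are AR(1)-smoothed Gaussian samples whose stationary spatial
#' covariance equals the group covariance from [make_group_covariance()].
#' Voxel series replicate their region signal plus independent Gaussian noise.
#' Motion (6 smoothed random walks), CSF and WM confound series are injected
#' additively with per-region random loadings, into both region and voxel
#' series (voxels inherit their region's loading).
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `mkl_cohort`: list with `spec`, `atlas` and
#'   `subjects` (each a `subject_data` list holding `region_series`,
#'   `voxel_series`, `voxel_to_region`, `motion`, `csf`, `wm`, `group`,
#'   `subject_id`, `TR`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  atlas <- cohort_atlas(spec)
  Tn <- spec$T_vol; R <- spec$n_regions; V <- spec$voxels_per_region
  chol_by_group <- list(
    patient = chol(make_group_covariance(spec, "patient")),
    control = chol(make_group_covariance(spec, "control")))
  groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  ids <- sprintf("sub-%03d", seq_along(groups))
  phi <- spec$ar_coef
  v2r <- data.frame(voxel = seq_len(R * V),
                    region_id = rep(seq_len(R), each = V))
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    L <- chol_by_group[[groups[i]]]
    ## stationary AR(1) with spatial covariance sigma
    z <- matrix(rnorm(Tn * R), Tn, R)
    x <- matrix(0, Tn, R)
    x[1, ] <- z[1, , drop = FALSE] %*% L
    innov_scale <- sqrt(1 - phi^2)
    e <- (z %*% L) * innov_scale
    for (t in 2:Tn) x[t, ] <- phi * x[t - 1, ] + e[t, ]
    ## confound series
    motion <- sapply(1:6, function(j) scale_to_sd(smooth_ma(cumsum(rnorm(Tn))),
                                                  spec$motion_amp))
    csf <- scale_to_sd(smooth_ma(rnorm(Tn), 7L), spec$csf_wm_amp)
    wm <- scale_to_sd(smooth_ma(rnorm(Tn), 7L), spec$csf_wm_amp)
    ## per-region loadings (voxels inherit their region's loading)
    load_m <- matrix(rnorm(R * 6, sd = 1 / sqrt(6)), R, 6)
    load_c <- rnorm(R); load_w <- rnorm(R)
    nuis <- motion %*% t(load_m) + outer(csf, load_c) + outer(wm, load_w)
    region_series <- x + nuis
    voxel_series <- region_series[, v2r$region_id, drop = FALSE] +
      matrix(rnorm(Tn * R * V, sd = spec$voxel_noise_sd), Tn, R * V)
    colnames(region_series) <- atlas$label
    colnames(voxel_series) <- paste0("vox_", sprintf("%05d", v2r$voxel))
    subjects[[i]] <- structure(
      list(subject_id = ids[i], group = groups[i],
           region_series = region_series, voxel_series = voxel_series,
           voxel_to_region = v2r,
           motion = motion, csf = csf, wm = wm, TR = spec$TR),
      class = "subject_data")
  }
  structure(list(spec = spec, atlas = atlas, subjects = subjects),
            class = "mkl_cohort")
}

#' @export
print.mkl_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d patients + %d controls, %d regions x %d voxels, T = %d (TR = %g s)\n",
              x$spec$n_patients, x$spec$n_controls, x$spec$n_regions,
              x$spec$voxels_per_region, x$spec$T_vol, x$spec$TR))
  invisible(x)
}

#' Group labels of a cohort
#' @param cohort an `mkl_cohort`.
#' @return character vector, one of `"patient"`/`"control"` per subject.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}

# Cohort serialization ---------------------------------------------------------

#' Write / read a cohort as delimited matrices with JSON sidecars
#'
#' One CSV per series per subject plus a JSON sidecar (subject id, group, TR,
#' voxel-to-region assignment) and a cohort-level JSON manifest. The round
#' trip `read_cohort(write_cohort(x))` reproduces `x` to full stored
#' precision.
#'
#' @param cohort an `mkl_cohort`.
#' @param dir output directory (created if absent).
#' @return `write_cohort` returns the manifest path invisibly; `read_cohort`
#'   returns an `mkl_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    base <- file.path(dir, s$subject_id)
    data.table::fwrite(data.table::as.data.table(s$region_series),
                       paste0(base, "_region.csv"))
    data.table::fwrite(data.table::as.data.table(s$voxel_series),
                       paste0(base, "_voxel.csv"))
    data.table::fwrite(data.table::as.data.table(s$motion),
                       paste0(base, "_motion.csv"))
    data.table::fwrite(data.frame(csf = s$csf, wm = s$wm),
                       paste0(base, "_nuisance.csv"))
    jsonlite::write_json(list(subject_id = s$subject_id, group = s$group,
                              TR = s$TR,
                              preprocessed = isTRUE(s$preprocessed),
                              voxel_to_region = s$voxel_to_region),
                         paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(subjects = vapply(cohort$subjects, `[[`,
                                              character(1), "subject_id"),
                            spec = unclass(cohort$spec),
                            atlas = cohort$atlas),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop(sprintf("no manifest.json in '%s'", dir), call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  spec <- man$spec
  spec$T_vol <- as.integer(spec$T_vol)
  spec <- do.call(cohort_spec, spec[setdiff(names(spec), character(0))])
  subjects <- lapply(man$subjects, function(id) {
    base <- file.path(dir, id)
    side_path <- paste0(base, ".json")
    if (!file.exists(side_path))
      stop(sprintf("missing sidecar '%s'", side_path), call. = FALSE)
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    for (field in c("subject_id", "group", "TR", "voxel_to_region"))
      if (is.null(side[[field]]))
        stop(sprintf("sidecar '%s' lacks field '%s'", side_path, field),
             call. = FALSE)
    if (!side$group %in% c("patient", "control"))
      stop(sprintf("sidecar '%s': group '%s' is not 'patient' or 'control'",
                   side_path, side$group), call. = FALSE)
    nuis <- as.matrix(data.table::fread(paste0(base, "_nuisance.csv")))
    structure(
      list(subject_id = side$subject_id, group = side$group,
           region_series = as.matrix(data.table::fread(paste0(base, "_region.csv"))),
           voxel_series = as.matrix(data.table::fread(paste0(base, "_voxel.csv"))),
           voxel_to_region = as.data.frame(side$voxel_to_region),
           motion = unname(as.matrix(data.table::fread(paste0(base, "_motion.csv")))),
           csf = nuis[, "csf"], wm = nuis[, "wm"], TR = side$TR,
           preprocessed = isTRUE(side$preprocessed)),
      class = "subject_data")
  })
  structure(list(spec = spec, atlas = man$atlas, subjects = subjects),
            class = "mkl_cohort")
}

#' Export a cohort's voxel series as NIfTI volumes with an integer atlas
#'
#' Voxels are laid out on a `V x R x 1` grid (voxel-within-region by region),
#' giving a 4D series volume per subject plus one integer label volume.
#' Requires the RNifti package.
#'
#' @param cohort an `mkl_cohort`.
#' @param dir output directory.
#' @return invisible vector of file paths written.
#' @export
export_cohort_nifti <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  V <- cohort$spec$voxels_per_region; R <- cohort$spec$n_regions
  Tn <- cohort$spec$T_vol
  atlas_vol <- array(rep(seq_len(R), each = V), dim = c(V, R, 1))
  atlas_path <- file.path(dir, "atlas.nii")
  RNifti::writeNifti(RNifti::asNifti(atlas_vol), atlas_path)
  paths <- vapply(cohort$subjects, function(s) {
    vol <- array(0, dim = c(V, R, 1, Tn))
    for (t in seq_len(Tn)) vol[, , 1, t] <- matrix(s$voxel_series[t, ], V, R)
    p <- file.path(dir, paste0(s$subject_id, "_bold.nii"))
    RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), p)
    p
  }, character(1))
  invisible(c(atlas_path, paths))
}

#' Re-parcellate an exported NIfTI series by atlas labels
#'
#' @param bold_path path to a 4D NIfTI series written by
#'   [export_cohort_nifti()].
#' @param atlas_path path to the matching integer label volume.
#' @return T x n_regions matrix of within-label voxel means.
#' @export
reparcellate_nifti <- function(bold_path, atlas_path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI import requires the RNifti package", call. = FALSE)
  vol <- RNifti::readNifti(bold_path)
  atl <- round(as.vector(RNifti::readNifti(atlas_path)))
  d <- dim(vol); Tn <- d[4]
  flat <- matrix(vol, prod(d[1:3]), Tn)
  labs <- sort(unique(atl))
  out <- vapply(labs, function(l) colMeans(flat[atl == l, , drop = FALSE]),
                numeric(Tn))
  colnames(out) <- as.character(labs)
  out
}

#' Desk-scale cohort presets
#'
#' Reduced-size study conditions used by the analysis scripts and the test
#' suite, so whole-pipeline runs complete in minutes on one CPU while
#' keeping the full cohort size (40 patients, 30 controls) and acquisition
#' length (180 volumes at TR = 3 s).
#'
#' `"classification"`: 10 regions (4 cortical motor, 4 subcortical motor,
#' 2 non-motor), 4 voxels per region, strong connectivity effects
#' (`delta1 = 0.3`, `delta2 = 0.25`, `delta3 = 0.25`) and moderate nuisance
#' amplitudes (0.5). `"network"`: 30 regions (4 cortical motor, 6
#' subcortical motor, 20 non-motor), 1 voxel per region, with a large
#' subcortical-to-cortical decoupling (`delta2`), the construction whose
#' group contrast mirrors the reported motor degree / path-length /
#' assortativity differences. `"null"`: the classification preset with all
#' deltas at 0 (no group difference).
#'
#' @param kind preset name.
#' @param seed integer seed.
#' @param ... overrides passed to [cohort_spec()].
#' @return a [cohort_spec()].
#' @export
desk_cohort_spec <- function(kind = c("classification", "network", "null"),
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  args <- switch(kind,
    classification = list(n_patients = 40L, n_controls = 30L,
                          n_regions = 10L, n_motor_cortical = 4L,
                          n_motor_subcortical = 4L, voxels_per_region = 4L,
                          base_coupling = 0.35, delta1 = 0.30, delta2 = 0.25,
                          delta3 = 0.25, motion_amp = 0.5, csf_wm_amp = 0.5,
                          voxel_noise_sd = 0.5),
    null = list(n_patients = 40L, n_controls = 30L,
                n_regions = 10L, n_motor_cortical = 4L,
                n_motor_subcortical = 4L, voxels_per_region = 4L,
                base_coupling = 0.35, delta1 = 0, delta2 = 0, delta3 = 0,
                motion_amp = 0.5, csf_wm_amp = 0.5, voxel_noise_sd = 0.5),
    network = list(n_patients = 20L, n_controls = 20L,
                   n_regions = 30L, n_motor_cortical = 4L,
                   n_motor_subcortical = 6L, voxels_per_region = 1L,
                   base_coupling = 0.35, delta1 = 0.30, delta2 = 0.15,
                   delta3 = 0.10, motion_amp = 0.5, csf_wm_amp = 0.5,
                   voxel_noise_sd = 0.5))
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(cohort_spec, args)
}

#' Planted-optimum graph cohorts for threshold selection
#'
#' Builds per-subject weighted graphs sharing a fixed backbone edge set of
#' exactly `ceiling(alpha_star * n(n-1)/2)` edges (a ring lattice plus fixed
#' shortcuts) with strong weights, while all remaining pairs carry weaker
#' subject-specific random weights. At threshold `alpha_star` every subject
#' retains exactly the backbone, so the small-world ratio is maximally
#' consistent across subjects there.
#'
#' @param n_subjects number of subject graphs.
#' @param n_nodes nodes per graph.
#' @param alpha_star planted retention fraction.
#' @param lattice_k even ring-lattice neighbor count.
#' @param seed integer seed.
#' @return list of symmetric weight matrices (zero diagonal).
#' @export
simulate_planted_threshold_graphs <- function(n_subjects = 8L, n_nodes = 40L,
                                              alpha_star = 0.2, lattice_k = 6L,
                                              seed = 1L) {
  set.seed(seed)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  quota <- ceiling(alpha_star * n_pairs)
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  ring_dist <- pmin(abs(pairs[, 1] - pairs[, 2]),
                    n_nodes - abs(pairs[, 1] - pairs[, 2]))
  lattice <- which(ring_dist <= lattice_k / 2)
  if (length(lattice) > quota)
    stop("lattice alone exceeds the planted quota; lower lattice_k", call. = FALSE)
  extra <- sample(setdiff(seq_len(nrow(pairs)), lattice),
                  quota - length(lattice))
  backbone <- c(lattice, extra)
  lapply(seq_len(n_subjects), function(i) {
    ## sub-backbone weights carry a subject-specific module structure, so
    ## above the planted threshold the retained topologies diverge across
    ## subjects while at alpha_star every subject retains exactly the backbone
    n_modules <- sample(2:8, 1)
    membership <- sample(rep(seq_len(n_modules), length.out = n_nodes))
    same_module <- membership[pairs[, 1]] == membership[pairs[, 2]]
    w <- ifelse(same_module, runif(nrow(pairs), 0.45, 0.69),
                runif(nrow(pairs), 0, 0.45))
    w[backbone] <- runif(length(backbone), 0.7, 1)
    m <- matrix(0, n_nodes, n_nodes)
    m[upper.tri(m)] <- w
    m + t(m)
  })
}
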