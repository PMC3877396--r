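# End-to-end pipeline: simulate -> preprocess -> features -> classify ->
# permutation test -> network analysis -> group maps ---------------------------

#' Default pipeline configuration
#'
#' All stage toggles and module parameters in one list. Stage seeds are
#' derived from the single global seed via [stage_seed()], so stages can be
#' rerun in isolation reproducibly.
#'
#' @param seed global integer seed.
#' @param out_dir output directory (`NULL` for no file output).
#' @param spec a [cohort_spec()]; its own seed is overridden by the derived
#'   simulate-stage seed.
#' @param stages character vector of stages to run, in pipeline order.
#' @param C_grid,gamma_grid classifier hyperparameter grids.
#' @param k PCA scores per (seed, ROI) block.
#' @param pca_mode `"cohort"` (cohort-wide PCA) or `"fold_safe"`.
#' @param B permutation count for the classifier null.
#' @param alpha_grid candidate proportional thresholds.
#' @param q FDR level for the network group tests.
#' @param stat_seed_id seed id (or index) whose maps enter the voxelwise
#'   group comparison; `NULL` picks the first seed.
#' @param p_thresh,extent_min,n_perm voxel threshold, cluster extent and
#'   permutation count of the cluster correction.
#' @return a named configuration list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            spec = cohort_spec(),
                            stages = c("simulate", "preprocess", "features",
                                       "classify", "permtest", "cna",
                                       "groupstats"),
                            C_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2),
                            k = 10L, pca_mode = "cohort",
                            B = 1000L,
                            alpha_grid = seq(0.05, 0.5, by = 0.05),
                            q = 0.05,
                            stat_seed_id = NULL,
                            p_thresh = 0.001, extent_min = 5L,
                            n_perm = 1000L) {
  list(seed = as.integer(seed), out_dir = out_dir, spec = spec,
       stages = stages, C_grid = C_grid, gamma_grid = gamma_grid,
       k = as.integer(k), pca_mode = pca_mode, B = as.integer(B),
       alpha_grid = alpha_grid, q = q, stat_seed_id = stat_seed_id,
       p_thresh = p_thresh, extent_min = as.integer(extent_min),
       n_perm = as.integer(n_perm))
}

#' Run the full pipeline from one configuration
#'
#' Stages execute in order; each consumes the previous stage's in-memory
#' output, and a stage whose inputs are missing (e.g. `permtest` without
#' `classify`) halts the run with the failing stage named. The returned
#' report collects every stage's headline results and is also written as
#' JSON (with the configuration and seed) when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return a run report list with one element per executed stage.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  report <- list(seed = config$seed,
                 config_hash = digest_config(config),
                 stages_run = character(0))
  state <- new.env(parent = emptyenv())
  need <- function(what, stage) {
    if (!exists(what, envir = state))
      stop(sprintf("stage '%s' requires output of a stage that did not run ('%s' missing)",
                   stage, what), call. = FALSE)
    get(what, envir = state)
  }

  for (stage in config$stages) {
    switch(stage,
      simulate = {
        spec <- config$spec
        spec$seed <- stage_seed(config$seed, "simulate")
        cohort <- generate_cohort(spec)
        assign("cohort", cohort, envir = state)
        report$simulate <- list(n_subjects = length(cohort$subjects),
                                n_patients = spec$n_patients,
                                n_controls = spec$n_controls,
                                n_regions = spec$n_regions,
                                T_vol = spec$T_vol, seed = spec$seed)
      },
      preprocess = {
        cohort <- preprocess_cohort(need("cohort", "preprocess"))
        assign("cohort", cohort, envir = state)
        report$preprocess <- list(band = c(0.03, 0.06), order = 4,
                                  zero_phase = TRUE)
      },
      features = {
        cohort <- need("cohort", "features")
        cmaps <- cohort_seed_maps(cohort)
        ft <- suppressMessages(pca_reduce_maps(cmaps, k = config$k,
                                               mode = "cohort"))
        assign("cmaps", cmaps, envir = state)
        assign("features", ft, envir = state)
        report$features <- list(n_seeds = nrow(cmaps$seeds),
                                n_features = ncol(ft$matrix),
                                k = config$k, mode = config$pca_mode)
      },
      classify = {
        cohort <- need("cohort", "classify")
        x <- if (identical(config$pca_mode, "fold_safe"))
          need("cmaps", "classify") else need("features", "classify")
        cv <- nested_loo_evaluate(x, cohort_labels(cohort),
                                  C_grid = config$C_grid,
                                  gamma_grid = config$gamma_grid,
                                  k = config$k)
        assign("cv", cv, envir = state)
        report$classify <- list(accuracy = cv$accuracy,
                                inner_accuracy = cv$inner_accuracy,
                                sensitivity = cv$sensitivity,
                                specificity = cv$specificity,
                                peak_rois_mean = cv$peak_rois_mean,
                                peak_rois_sd = cv$peak_rois_sd)
      },
      permtest = {
        cv <- need("cv", "permtest")
        ft <- need("features", "permtest")
        cohort <- need("cohort", "permtest")
        labels <- cohort_labels(cohort)
        perms <- balanced_permutations(labels, B = config$B,
                                       seed = stage_seed(config$seed, "permtest"))
        nd <- null_distribution(ft, labels, perms,
                                C = stats::median(cv$selected_C),
                                gamma = stats::median(cv$selected_gamma),
                                observed = cv$accuracy)
        assign("null", nd, envir = state)
        report$permtest <- list(p_value = nd$p_value, B = nd$B,
                                observed = nd$observed)
      },
      cna = {
        cohort <- need("cohort", "cna")
        graphs <- lapply(cohort$subjects, function(s)
          build_connectivity_graph(s$region_series))
        sel <- select_threshold(graphs, alpha_grid = config$alpha_grid,
                                seed = stage_seed(config$seed, "cna"))
        cna <- network_group_analysis(cohort, alpha = sel$alpha_star,
                                      q = config$q)
        assign("cna", cna, envir = state)
        report$cna <- list(alpha_star = sel$alpha_star,
                           local = cna$local[, c("variable", "t", "p", "p_adj",
                                                 "significant")],
                           global = cna$global[, c("variable", "t", "p",
                                                   "p_adj", "significant")])
      },
      groupstats = {
        cmaps <- need("cmaps", "groupstats")
        cohort <- need("cohort", "groupstats")
        seed_id <- config$stat_seed_id %||% cmaps$seeds$seed_id[1]
        maps <- seed_map_matrix(cmaps, seed_id)
        res <- cluster_correct(maps, cohort_labels(cohort),
                               adjacency = chain_adjacency(ncol(maps)),
                               p_thresh = config$p_thresh,
                               extent_min = config$extent_min,
                               n_perm = config$n_perm,
                               seed = stage_seed(config$seed, "groupstats"))
        report$groupstats <- list(seed_id = seed_id,
                                  n_clusters = length(res$clusters),
                                  cluster_extents = vapply(res$clusters, `[[`,
                                                           numeric(1), "extent"),
                                  cluster_p = vapply(res$clusters, `[[`,
                                                     numeric(1), "p_corrected"))
      },
      stop(sprintf("unknown stage '%s'", stage), call. = FALSE))
    report$stages_run <- c(report$stages_run, stage)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(serializable_config(config),
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

serializable_config <- function(config) {
  config$spec <- unclass(config$spec)
  config
}

digest_config <- function(config) {
  s <- paste(deparse(serializable_config(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 4294967295)
}
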