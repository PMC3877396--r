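# Complex-network analysis of parcellated connectivity graphs -----------------
#
# ROI-mean series (already band-limited) give a Pearson correlation matrix
# per subject; negative and self correlations are pruned, the graph is
# binarized by proportional thresholding (top fraction alpha of all possible
# node pairs), and degree, clustering, path length, small-world ratio and
# binary assortativity are compared between groups with Welch t-tests under
# Benjamini-Hochberg FDR control.

#' Unthresholded connectivity graph from region series
#'
#' @param region_series T x n matrix of (preprocessed) ROI series.
#' @return `connectivity_graph`: list with `weights` (symmetric, zero
#'   diagonal, negative correlations pruned to 0) and `labels`. Zero-variance
#'   regions have their row/column zeroed (logged).
#' @export
build_connectivity_graph <- function(region_series) {
  assert_matrix(region_series)
  sds <- apply(region_series, 2, sd)
  zero_var <- sds == 0
  w <- suppressWarnings(cor(region_series))
  w[is.na(w)] <- 0
  w[zero_var, ] <- 0; w[, zero_var] <- 0
  w[w < 0] <- 0
  diag(w) <- 0
  out <- structure(list(weights = w, adjacency = NULL, alpha = NULL,
                        labels = colnames(region_series)),
                   class = "connectivity_graph")
  if (any(zero_var))
    out <- log_note(out, sprintf("%d zero-variance region(s) disconnected",
                                 sum(zero_var)))
  out
}

#' Proportional thresholding to a binary adjacency
#'
#' Keeps the `ceiling(alpha * n(n-1)/2)` strongest positive weights (ties:
#' the lexicographically smaller node pair first) and binarizes. If fewer
#' positive weights exist than the quota, all are kept and the shortfall
#' logged.
#'
#' @param graph a `connectivity_graph`.
#' @param alpha retained fraction of all possible node pairs, in `(0, 1]`.
#' @return the graph with `adjacency` (binary symmetric) and `alpha` filled.
#' @export
threshold_proportional <- function(graph, alpha) {
  stopifnot(inherits(graph, "connectivity_graph"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]", call. = FALSE)
  w <- graph$weights
  n <- nrow(w)
  quota <- ceiling(alpha * n * (n - 1) / 2)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[ut]
  pos <- wt > 0
  ord <- order(-wt[pos], ut[pos, 1], ut[pos, 2])
  keep_n <- min(quota, sum(pos))
  keep <- which(pos)[ord[seq_len(keep_n)]]
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(w)
  graph$adjacency <- adj
  graph$alpha <- alpha
  if (keep_n < quota)
    graph <- log_note(graph, sprintf("alpha = %g: only %d positive weights for a quota of %d",
                                     alpha, keep_n, quota))
  graph
}

as_igraph <- function(adjacency) {
  igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
}

#' Node and global metrics of a binary graph
#'
#' Degree, per-node clustering (triangle fraction; 0 for degree < 2),
#' per-node path length (mean of finite breadth-first shortest-path
#' distances to the other nodes; unreachable pairs are excluded and
#' counted), the characteristic path length (mean over node values) and the
#' global clustering coefficient (mean over nodes).
#'
#' @param adjacency binary symmetric matrix (or a thresholded
#'   `connectivity_graph`).
#' @return `cna_metrics`: list with `degree`, `clustering`, `path_length`
#'   (per node), `global_clustering`, `char_path_length`,
#'   `disconnected_pairs`.
#' @export
graph_metrics <- function(adjacency) {
  if (inherits(adjacency, "connectivity_graph")) adjacency <- adjacency$adjacency
  assert_matrix(adjacency)
  n <- nrow(adjacency)
  if (n == 0L || sum(adjacency) == 0) stop("empty graph", call. = FALSE)
  g <- as_igraph(adjacency)
  deg <- rowSums(adjacency)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  d <- igraph::distances(g)
  diag(d) <- NA
  finite <- is.finite(d)
  path_length <- vapply(seq_len(n), function(i) {
    di <- d[i, ]
    di <- di[!is.na(di) & is.finite(di)]
    if (length(di)) mean(di) else NA_real_
  }, numeric(1))
  disconnected <- sum(!finite & !is.na(d)) / 2
  structure(list(degree = deg, clustering = cl, path_length = path_length,
                 global_clustering = mean(cl),
                 char_path_length = mean(path_length, na.rm = TRUE),
                 disconnected_pairs = disconnected,
                 labels = rownames(adjacency)),
            class = "cna_metrics")
}

#' Small-world ratio against degree-preserving rewired nulls
#'
#' `sigma = (C / C_rand) / (L / L_rand)`, with clustering and characteristic
#' path length computed on the largest connected component and the null
#' values averaged over `n_null` degree-preserving rewirings (10 swap
#' attempts per edge).
#'
#' @param adjacency binary symmetric matrix or thresholded
#'   `connectivity_graph`.
#' @param n_null null-ensemble size (default 20).
#' @param rewires_per_edge swap attempts per edge (default 10).
#' @param seed optional integer seed for the rewiring RNG.
#' @return the small-world ratio (positive scalar).
#' @export
small_world_sigma <- function(adjacency, n_null = 20L, rewires_per_edge = 10L,
                              seed = NULL) {
  if (inherits(adjacency, "connectivity_graph")) adjacency <- adjacency$adjacency
  if (!is.null(seed)) set.seed(seed)
  if (n_null < 1L) stop("n_null must be at least 1", call. = FALSE)
  g <- as_igraph(adjacency)
  comp <- igraph::components(g)
  giant <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, giant)
  ne <- igraph::ecount(g)
  if (ne < 2L || igraph::vcount(g) < 4L)
    stop("graph too sparse to rewire for the small-world null", call. = FALSE)
  metr <- function(gr) {
    c(C = mean(igraph::transitivity(gr, type = "localundirected",
                                    isolates = "zero")),
      L = {
        d <- igraph::distances(gr)
        diag(d) <- NA
        mean(apply(d, 1, function(x) mean(x[is.finite(x)], na.rm = TRUE)),
             na.rm = TRUE)
      })
  }
  obs <- metr(g)
  nulls <- vapply(seq_len(n_null), function(b) {
    metr(igraph::rewire(g, igraph::keeping_degseq(niter = rewires_per_edge * ne)))
  }, numeric(2))
  c_rand <- mean(nulls["C", ])
  l_rand <- mean(nulls["L", ])
  if (!is.finite(c_rand) || c_rand <= 0 || !is.finite(l_rand) || l_rand <= 0)
    stop("degenerate rewired null ensemble (zero clustering or path length)",
         call. = FALSE)
  (obs["C"] / c_rand) / (obs["L"] / l_rand)
}

#' Binary degree assortativity
#'
#' Pearson correlation of end-node degrees over the directed edge list (each
#' undirected edge counted in both directions). Positive values mean hubs
#' connect to hubs.
#'
#' @param adjacency binary symmetric matrix or thresholded
#'   `connectivity_graph`.
#' @return assortativity in `[-1, 1]`, or `NA` with a warning for graphs
#'   where it is undefined (fewer than 2 edges, or zero degree variance over
#'   edge endpoints, e.g. regular graphs).
#' @export
assortativity_binary <- function(adjacency) {
  if (inherits(adjacency, "connectivity_graph")) adjacency <- adjacency$adjacency
  assert_matrix(adjacency)
  deg <- rowSums(adjacency)
  e <- which(upper.tri(adjacency) & adjacency > 0, arr.ind = TRUE)
  if (nrow(e) < 2L) {
    warning("assortativity undefined: fewer than 2 edges", call. = FALSE)
    return(NA_real_)
  }
  x <- c(deg[e[, 1]], deg[e[, 2]])
  y <- c(deg[e[, 2]], deg[e[, 1]])
  if (sd(x) == 0 || sd(y) == 0) {
    warning("assortativity undefined: zero degree variance over edge endpoints",
            call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)
}

#' Select the proportional threshold by the small-world signal-to-noise rule
#'
#' For every candidate `alpha`, the small-world ratio is computed per subject
#' graph and the `alpha` maximizing `mean(sigma) / sd(sigma)` across subjects
#' is selected (sd with denominator n - 1; ties toward the smaller `alpha`;
#' a zero sd yields an infinite ratio, capped at 1e12 and logged). Candidate
#' thresholds failing for any subject (e.g. too sparse to rewire) are skipped
#' and logged.
#'
#' @param graphs list of unthresholded `connectivity_graph`s (or weight
#'   matrices).
#' @param alpha_grid candidate retention fractions (default
#'   `seq(0.05, 0.5, by = 0.05)`).
#' @param n_null,rewires_per_edge passed to [small_world_sigma()].
#' @param seed integer seed for the rewiring RNG.
#' @return list with `alpha_star`, `table` (per-alpha mean, sd, ratio) and
#'   `sigma` (subjects x alpha matrix); notes in [run_log()].
#' @export
select_threshold <- function(graphs, alpha_grid = seq(0.05, 0.5, by = 0.05),
                             n_null = 20L, rewires_per_edge = 10L, seed = 1L) {
  if (!length(alpha_grid)) stop("alpha_grid must be non-empty", call. = FALSE)
  graphs <- lapply(graphs, function(g) {
    if (inherits(g, "connectivity_graph")) g
    else structure(list(weights = g, adjacency = NULL, alpha = NULL,
                        labels = rownames(g)), class = "connectivity_graph")
  })
  set.seed(seed)
  notes <- character(0)
  sig <- matrix(NA_real_, length(graphs), length(alpha_grid),
                dimnames = list(NULL, alpha_grid))
  for (a in seq_along(alpha_grid)) {
    ok <- TRUE
    for (s in seq_along(graphs)) {
      v <- tryCatch(
        small_world_sigma(threshold_proportional(graphs[[s]], alpha_grid[a]),
                          n_null = n_null, rewires_per_edge = rewires_per_edge),
        error = function(e) NA_real_)
      if (is.na(v)) { ok <- FALSE; break }
      sig[s, a] <- v
    }
    if (!ok) {
      sig[, a] <- NA_real_
      notes <- c(notes, sprintf("alpha = %g skipped: small-world ratio failed for a subject",
                                alpha_grid[a]))
    }
  }
  means <- colMeans(sig)
  sds <- apply(sig, 2, sd)
  ratio <- ifelse(sds == 0, Inf, means / sds)
  if (any(is.finite(means) & sds == 0, na.rm = TRUE)) {
    notes <- c(notes, "zero across-subject sd at some alpha; ratio capped at 1e12")
    ratio[is.infinite(ratio)] <- 1e12
  }
  valid <- which(!is.na(ratio))
  if (!length(valid)) stop("no candidate threshold was computable", call. = FALSE)
  alpha_star <- alpha_grid[valid[which.max(ratio[valid])]]
  out <- list(alpha_star = alpha_star,
              table = data.frame(alpha = alpha_grid, mean_sigma = means,
                                 sd_sigma = sds, ratio = ratio),
              sigma = sig)
  for (nt in notes) out <- log_note(out, nt)
  out
}

#' Welch t-tests with Benjamini-Hochberg correction per family
#'
#' One Welch two-sample t-test per column of `values`, with BH step-up
#' correction applied within each family of columns at level `q`. Columns
#' constant in both groups are skipped (logged).
#'
#' @param values subjects x variables numeric matrix.
#' @param labels two-class labels, one per subject (positive class
#'   `"patient"` when present).
#' @param family optional grouping vector over columns (BH within family;
#'   default one family).
#' @param q FDR level (default 0.05).
#' @return data.frame with per-variable group means, Welch `t`, `df`, `p`,
#'   BH-adjusted `p_adj` and `significant`.
#' @export
compare_groups_fdr <- function(values, labels, family = NULL, q = 0.05) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  ## NA cells are allowed (e.g. path length of an isolated node) and are
  ## dropped per group inside each test
  y <- as_svm_labels(labels)
  if (min(table(y)) < 2L) stop("both groups must have at least 2 subjects",
                               call. = FALSE)
  family <- family %||% rep("all", ncol(values))
  res <- lapply(seq_len(ncol(values)), function(j) {
    a <- values[y == 1L, j]; b <- values[y == -1L, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]  # e.g. isolated-node path lengths
    if (length(a) < 2L || length(b) < 2L ||
        (sd(a) == 0 && sd(b) == 0))
      return(data.frame(variable = colnames(values)[j] %||% as.character(j),
                        family = family[j], mean_patient = mean(a),
                        mean_control = mean(b), t = NA_real_, df = NA_real_,
                        p = NA_real_))
    tt <- stats::t.test(a, b)
    data.frame(variable = colnames(values)[j] %||% as.character(j),
               family = family[j], mean_patient = mean(a),
               mean_control = mean(b), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- NA_real_
  for (f in unique(tab$family)) {
    idx <- tab$family == f & !is.na(tab$p)
    tab$p_adj[idx] <- p.adjust(tab$p[idx], method = "BH")
  }
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < q
  skipped <- sum(is.na(tab$p))
  if (skipped > 0)
    tab <- log_note(tab, sprintf("%d constant metric column(s) skipped", skipped))
  tab
}

#' Per-subject graph metrics for a preprocessed cohort
#'
#' Builds each subject's pruned connectivity graph from the ROI series,
#' thresholds at `alpha` and collects node degree, node path length and
#' global binary assortativity.
#'
#' @param cohort a preprocessed `mkl_cohort`.
#' @param alpha proportional threshold.
#' @return list with matrices `degree` and `path_length` (subjects x
#'   regions), vector `assortativity`, and `labels` (group label per
#'   subject).
#' @export
subject_graph_metrics <- function(cohort, alpha) {
  labels <- cohort_labels(cohort)
  region_names <- cohort$atlas$label
  mets <- lapply(cohort$subjects, function(s) {
    g <- threshold_proportional(build_connectivity_graph(s$region_series), alpha)
    m <- graph_metrics(g)
    list(degree = m$degree, path_length = m$path_length,
         assort = suppressWarnings(assortativity_binary(g)))
  })
  deg <- do.call(rbind, lapply(mets, `[[`, "degree"))
  pl <- do.call(rbind, lapply(mets, `[[`, "path_length"))
  colnames(deg) <- colnames(pl) <- region_names
  list(degree = deg, path_length = pl,
       assortativity = vapply(mets, `[[`, numeric(1), "assort"),
       labels = labels)
}

#' Motor-ROI and global group comparison of network metrics
#'
#' Reproduces the local (degree, path length over the motor ROIs, BH over the
#' ROI family per metric) and global (assortativity per threshold-grid point,
#' BH over grid points) group tests.
#'
#' @param cohort a preprocessed `mkl_cohort`.
#' @param alpha selected proportional threshold for the local tests.
#' @param alpha_grid thresholds at which the global assortativity test is
#'   repeated.
#' @param motor_rois region labels of the motor ROI family (default left and
#'   right M1 and SMA).
#' @param q FDR level.
#' @return list with `local` and `global` discovery tables
#'   (see [compare_groups_fdr()]).
#' @export
network_group_analysis <- function(cohort, alpha = 0.35,
                                   alpha_grid = NULL,
                                   motor_rois = c("precentral_L", "precentral_R",
                                                  "supp_motor_area_L",
                                                  "supp_motor_area_R"),
                                   q = 0.05) {
  sm <- subject_graph_metrics(cohort, alpha)
  motor_rois <- intersect(motor_rois, colnames(sm$degree))
  if (!length(motor_rois)) stop("no motor ROI labels found in the atlas",
                                call. = FALSE)
  local_vals <- cbind(sm$degree[, motor_rois, drop = FALSE],
                      sm$path_length[, motor_rois, drop = FALSE])
  colnames(local_vals) <- c(paste0("degree_", motor_rois),
                            paste0("path_length_", motor_rois))
  fam <- rep(c("degree", "path_length"), each = length(motor_rois))
  local_tab <- compare_groups_fdr(local_vals, sm$labels, family = fam, q = q)

  alpha_grid <- alpha_grid %||% alpha
  glob_vals <- vapply(alpha_grid, function(a) {
    if (a == alpha) sm$assortativity
    else subject_graph_metrics(cohort, a)$assortativity
  }, numeric(length(cohort$subjects)))
  glob_vals <- matrix(glob_vals, ncol = length(alpha_grid))
  colnames(glob_vals) <- paste0("assortativity_alpha_", alpha_grid)
  keep <- colSums(is.na(glob_vals)) == 0
  global_tab <- compare_groups_fdr(glob_vals[, keep, drop = FALSE], sm$labels,
                                   q = q)
  list(local = local_tab, global = global_tab, alpha = alpha,
       metrics = sm)
}
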