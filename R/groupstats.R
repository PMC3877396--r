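# Voxelwise group-difference maps ----------------------------------------------
#
# Welch two-sample t-statistics (unequal variances, Satterthwaite degrees of
# freedom) per voxel of a seed's correlation maps, with familywise control by
# a nonparametric maximum-cluster-extent permutation test: supra-threshold
# voxels (p below a fixed voxel-level threshold, two-sided) are grouped into
# connected components under the supplied voxel adjacency, components below
# the extent minimum dropped, and each surviving cluster assigned the
# fraction of label permutations whose own maximal extent reaches it.

#' Voxelwise Welch t-map
#'
#' @param maps subjects x voxels matrix (one seed's correlation maps).
#' @param labels two-class labels per subject (positive class first in the
#'   difference: `t > 0` means positive-class mean is larger).
#' @return `group_stat_map`: list with `t` (Welch statistic), `df`
#'   (Welch-Satterthwaite), `p` (two-sided), and `masked` (voxels with zero
#'   within-group variance in both groups, t set to 0 / p to 1, logged).
#' @export
welch_t_map <- function(maps, labels) {
  assert_matrix(maps)
  y <- as_svm_labels(labels)
  if (min(table(y)) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  a <- maps[y == 1L, , drop = FALSE]
  b <- maps[y == -1L, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
  se2 <- v1 / n1 + v2 / n2
  masked <- se2 == 0
  se2[masked] <- 1
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[masked] <- n1 + n2 - 2
  p <- 2 * pt(-abs(t_stat), df)
  t_stat[masked] <- 0; p[masked] <- 1
  out <- structure(list(t = t_stat, df = df, p = p, masked = masked,
                        n1 = n1, n2 = n2),
                   class = "group_stat_map")
  if (any(masked))
    out <- log_note(out, sprintf("%d zero-variance voxel(s) masked", sum(masked)))
  out
}

#' Chain adjacency for 1-D voxel strips
#' @param n_voxels number of voxels.
#' @return two-column edge matrix connecting consecutive voxels.
#' @export
chain_adjacency <- function(n_voxels) {
  if (n_voxels < 2L) return(matrix(integer(0), 0, 2))
  cbind(seq_len(n_voxels - 1L), 2:n_voxels)
}

#' 6-connectivity adjacency for a voxel grid
#' @param dims integer vector of grid dimensions (length 2 or 3).
#' @return two-column edge matrix over voxels in array (column-major) order.
#' @export
grid_adjacency <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  idx <- array(seq_len(prod(dims)), dim = dims)
  edges <- list(
    cbind(as.vector(idx[-dims[1], , , drop = FALSE]),
          as.vector(idx[-1, , , drop = FALSE])),
    cbind(as.vector(idx[, -dims[2], , drop = FALSE]),
          as.vector(idx[, -1, , drop = FALSE])),
    if (dims[3] > 1L)
      cbind(as.vector(idx[, , -dims[3], drop = FALSE]),
            as.vector(idx[, , -1, drop = FALSE])))
  do.call(rbind, Filter(Negate(is.null), edges))
}

## connected components of the supra-threshold voxel set
supra_clusters <- function(supra, adjacency) {
  voxels <- which(supra)
  if (!length(voxels)) return(list())
  keep <- adjacency[supra[adjacency[, 1]] & supra[adjacency[, 2]], ,
                    drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(match(keep, voxels), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, length(voxels) - igraph::vcount(g))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(cc) voxels[comp$membership == cc])
}

#' Permutation maximum-cluster-extent correction
#'
#' Thresholds the voxelwise p-map at `p_thresh`, groups supra-threshold
#' voxels into connected components under `adjacency`, drops components
#' smaller than `extent_min`, and assigns each surviving cluster a corrected
#' p-value: the add-one fraction of label permutations whose maximal
#' supra-threshold cluster extent reaches the observed extent.
#'
#' @param maps subjects x voxels matrix (same input as [welch_t_map()]).
#' @param labels group labels.
#' @param adjacency two-column voxel edge matrix ([chain_adjacency()],
#'   [grid_adjacency()], or custom).
#' @param p_thresh voxel-level two-sided p threshold (default 0.001).
#' @param extent_min minimum cluster extent in voxels (default 5).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return `cluster_result`: list with the observed `stat_map`, `clusters`
#'   (voxel sets, extents, corrected p), and the permutation `null_extents`.
#' @export
cluster_correct <- function(maps, labels, adjacency, p_thresh = 0.001,
                            extent_min = 5L, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  if (max(adjacency) > ncol(maps))
    stop("adjacency references voxels beyond the map", call. = FALSE)
  stat_map <- welch_t_map(maps, labels)
  obs_clusters <- supra_clusters(stat_map$p < p_thresh, adjacency)
  obs_clusters <- obs_clusters[lengths(obs_clusters) >= extent_min]

  labels <- as.character(labels)
  set.seed(seed)
  null_extents <- vapply(seq_len(n_perm), function(b) {
    perm <- sample(labels)
    pm <- welch_t_map(maps, perm)
    cl <- supra_clusters(pm$p < p_thresh, adjacency)
    if (length(cl)) max(lengths(cl)) else 0L
  }, numeric(1))

  clusters <- lapply(obs_clusters, function(vox) {
    extent <- length(vox)
    list(voxels = vox, extent = extent,
         p_corrected = (1 + sum(null_extents >= extent)) / (n_perm + 1))
  })
  structure(list(stat_map = stat_map, clusters = clusters,
                 null_extents = null_extents,
                 settings = list(p_thresh = p_thresh, extent_min = extent_min,
                                 n_perm = n_perm, seed = seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster-extent correction: %d cluster(s) at p < %g, extent >= %d (B = %d)\n",
              length(x$clusters), x$settings$p_thresh, x$settings$extent_min,
              x$settings$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  extent %d, corrected p = %.4g\n", cl$extent, cl$p_corrected))
  invisible(x)
}

#' Stack one seed's maps across a cohort
#'
#' @param cmaps a `cohort_maps`.
#' @param seed_id seed identifier (row of each subject's map matrix).
#' @return subjects x voxels matrix.
#' @export
seed_map_matrix <- function(cmaps, seed_id) {
  stopifnot(inherits(cmaps, "cohort_maps"))
  t(vapply(cmaps$maps, function(m) m$maps[seed_id, ],
           numeric(ncol(cmaps$maps[[1]]$maps))))
}
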