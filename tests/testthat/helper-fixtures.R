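# Shared fixture builders: everything is generated in code at test time.

## tiny cohort spec used across module tests
tiny_spec <- function(seed = 1L, ...) {
  desk_cohort_spec("classification", seed = seed,
                   n_patients = 5L, n_controls = 5L, T_vol = 120L, ...)
}

## feature table wrapper around a plain matrix
make_feature_table <- function(X, blocks, k = 1L) {
  structure(list(matrix = X, block_index = blocks,
                 roi_ids = unique(blocks), k = k, mode = "cohort",
                 subject_ids = sprintf("s%03d", seq_len(nrow(X)))),
            class = "feature_table")
}

## cleanly separable two-class feature table: class signal in the first block
separable_features <- function(n = 20L, p_per_block = 10L, n_blocks = 3L,
                               shift = 3, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p_per_block * n_blocks), n, p_per_block * n_blocks)
  labels <- rep(c("patient", "control"), length.out = n)
  X[labels == "patient", seq_len(p_per_block)] <-
    X[labels == "patient", seq_len(p_per_block)] + shift
  list(ft = make_feature_table(X, rep(seq_len(n_blocks), each = p_per_block)),
       labels = labels)
}

## hand-built subject with known series (counts as preprocessed)
make_subject <- function(region_series, voxel_series, v2r, TR = 3) {
  structure(list(subject_id = "sub-test", group = "patient",
                 region_series = region_series, voxel_series = voxel_series,
                 voxel_to_region = v2r,
                 motion = matrix(0, nrow(region_series), 6),
                 csf = numeric(nrow(region_series)),
                 wm = numeric(nrow(region_series)),
                 TR = TR, preprocessed = TRUE),
            class = "subject_data")
}

## independent all-pairs shortest-path oracle (Floyd-Warshall)
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- d[i, k] + d[k, ]
    d[i, ] <- pmin(d[i, ], nd)
  }
  d
}

## symmetric random binary graph
random_graph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}
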