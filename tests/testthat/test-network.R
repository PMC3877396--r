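# Connectivity graphs, thresholding, metrics, small-worldness, assortativity
# and the FDR group comparison.

test_that("connectivity graphs prune negatives and match the Pearson oracle", {
  set.seed(1)
  T_n <- 40
  x <- rnorm(T_n)
  series <- cbind(a = x, b = x, c = -x + rnorm(T_n, sd = 1e-8),
                  d = rnorm(T_n), e = rnorm(T_n))
  g <- build_connectivity_graph(series)
  expect_equal(g$weights["a", "b"], 1, tolerance = 1e-12)
  expect_identical(g$weights["a", "c"], 0)   # anti-correlation pruned
  expect_identical(unname(diag(g$weights)), rep(0, 5))
  cm <- cor(series)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(g$weights[i, j], max(cm[i, j], 0), tolerance = 1e-12)
  ## zero-variance region disconnected with a log note
  g2 <- build_connectivity_graph(cbind(series, f = rep(1, T_n)))
  expect_true(all(g2$weights["f", ] == 0))
  expect_match(run_log(g2), "zero-variance")
})

test_that("proportional thresholding retains the ceiling quota and nests", {
  set.seed(2)
  w <- matrix(0, 10, 10)
  w[upper.tri(w)] <- runif(45)
  w <- w + t(w)
  g <- structure(list(weights = w, adjacency = NULL, alpha = NULL,
                      labels = NULL), class = "connectivity_graph")
  t02 <- threshold_proportional(g, 0.2)
  expect_equal(sum(t02$adjacency) / 2, 9)   # ceiling(0.2 * 45)
  ## sorting oracle: exactly the 9 largest weights kept
  kept <- sort(w[upper.tri(w)], decreasing = TRUE)[1:9]
  expect_setequal(t02$weights[t02$adjacency == 1], kept)
  t_full <- threshold_proportional(g, 1)
  expect_true(all(t_full$adjacency[upper.tri(w)] == 1))
  ## monotone nesting along a grid
  prev <- matrix(0L, 10, 10)
  for (a in seq(0.1, 0.9, by = 0.2)) {
    cur <- threshold_proportional(g, a)$adjacency
    expect_true(all(cur[prev == 1] == 1))
    prev <- cur
  }
  ## shortfall: fewer positive weights than the quota
  w2 <- w; w2[w2 < 0.9] <- 0
  g2 <- structure(list(weights = w2, adjacency = NULL, alpha = NULL,
                       labels = NULL), class = "connectivity_graph")
  t2 <- threshold_proportional(g2, 0.9)
  expect_equal(sum(t2$adjacency) / 2, sum(w2[upper.tri(w2)] > 0))
  expect_match(run_log(t2), "quota")
})

test_that("graph metrics match hand counts and the Floyd-Warshall oracle", {
  k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
  m <- graph_metrics(k4)
  expect_equal(m$degree, rep(3, 4))
  expect_equal(m$clustering, rep(1, 4))
  expect_equal(m$char_path_length, 1)

  path5 <- matrix(0L, 5, 5)
  for (i in 1:4) { path5[i, i + 1] <- 1L; path5[i + 1, i] <- 1L }
  mp <- graph_metrics(path5)
  expect_equal(mp$degree, c(1, 2, 2, 2, 1))
  expect_equal(mp$char_path_length, 2.0)

  tri2 <- matrix(0L, 6, 6)
  tri2[1:3, 1:3] <- 1L; tri2[4:6, 4:6] <- 1L; diag(tri2) <- 0L
  mt <- graph_metrics(tri2)
  expect_equal(mt$path_length, rep(1, 6))
  expect_equal(mt$disconnected_pairs, 9)

  for (s in 1:5) {
    a <- random_graph(n = 20 + 2 * s, p = 0.15, seed = s)
    if (sum(a) == 0) next
    mm <- graph_metrics(a)
    d <- floyd_warshall(a)
    diag(d) <- NA
    oracle <- apply(d, 1, function(x) {
      x <- x[is.finite(x) & !is.na(x)]
      if (length(x)) mean(x) else NA_real_
    })
    expect_equal(mm$path_length, oracle)
    expect_equal(sum(mm$degree), sum(a))         # handshake
  }
  expect_error(graph_metrics(matrix(0L, 3, 3)), "empty")
})

test_that("the small-world ratio behaves on canonical graphs", {
  kc <- matrix(1L, 8, 8); diag(kc) <- 0L
  expect_equal(unname(small_world_sigma(kc, n_null = 3, seed = 1)), 1)
  ## a rewired member of its own null ensemble scores near 1
  g0 <- random_graph(30, 0.25, seed = 2)
  gg <- igraph::graph_from_adjacency_matrix(g0, mode = "undirected")
  set.seed(3)
  member <- igraph::as_adjacency_matrix(
    igraph::rewire(gg, igraph::keeping_degseq(niter = 10 * sum(g0) / 2)),
    sparse = FALSE)
  s_self <- small_world_sigma(member, n_null = 20, seed = 4)
  expect_gt(s_self, 0.8); expect_lt(s_self, 1.2)
  ## ring lattices with a few shortcuts are small-world (20-seed median)
  sigs <- sapply(1:20, function(s) {
    n <- 100
    a <- matrix(0L, n, n)
    for (d in 1:2) {
      idx <- cbind(1:n, ((1:n + d - 1) %% n) + 1)
      a[idx] <- 1L; a[idx[, 2:1]] <- 1L
    }
    set.seed(800 + s)
    gr <- igraph::rewire(igraph::graph_from_adjacency_matrix(a, "undirected"),
                         igraph::each_edge(p = 0.1))
    small_world_sigma(igraph::as_adjacency_matrix(gr, sparse = FALSE),
                      n_null = 8, seed = 800 + s)
  })
  expect_gt(median(sigs), 1)
  expect_error(small_world_sigma(matrix(0L, 5, 5) + diag(0L, 5), n_null = 2),
               "empty|sparse")
})

test_that("binary assortativity matches the edge-list Pearson definition", {
  star <- matrix(0L, 6, 6); star[1, 2:6] <- 1L; star[2:6, 1] <- 1L
  expect_equal(assortativity_binary(star), -1)
  cycle <- matrix(0L, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; cycle[i, j] <- 1L; cycle[j, i] <- 1L }
  expect_warning(r <- assortativity_binary(cycle), "undefined")
  expect_true(is.na(r))
  ## independent implementation check on 100 random graphs
  for (s in 1:100) {
    a <- random_graph(10, 0.4, seed = 1000 + s)
    gg <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    ref <- suppressWarnings(igraph::assortativity_degree(gg))
    mine <- suppressWarnings(assortativity_binary(a))
    if (is.na(ref) || is.na(mine)) next
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("threshold selection handles singleton and degenerate grids", {
  set.seed(5)
  graphs <- lapply(1:4, function(i) {
    w <- matrix(0, 20, 20)
    w[upper.tri(w)] <- runif(190, 0.2, 1)
    w + t(w)
  })
  sel1 <- select_threshold(graphs, alpha_grid = 0.35, n_null = 3, seed = 6)
  expect_equal(sel1$alpha_star, 0.35)
  ## identical graphs across subjects: zero sd, capped ratio wins
  same <- rep(graphs[1], 4)
  sel2 <- select_threshold(same, alpha_grid = c(0.3, 0.4), n_null = 1, seed = 7)
  expect_true(any(grepl("capped", run_log(sel2))) ||
                all(is.finite(sel2$table$ratio)))
  expect_true(sel2$alpha_star %in% c(0.3, 0.4))
})

test_that("group FDR tables follow the step-up oracle and the exact null", {
  set.seed(8)
  vals <- matrix(rnorm(40 * 6), 40, 6)
  vals[1:20, 1:2] <- vals[1:20, 1:2] + 2       # two real effects
  colnames(vals) <- paste0("m", 1:6)
  labels <- rep(c("patient", "control"), each = 20)
  tab <- compare_groups_fdr(vals, labels, q = 0.05)
  ## Welch oracle per column
  for (j in 1:6) {
    tt <- t.test(vals[1:20, j], vals[21:40, j])
    expect_equal(tab$p[j], tt$p.value, tolerance = 1e-12)
  }
  ## BH step-up oracle recomputed by hand from the returned p-values
  ord <- order(tab$p)
  thresh <- 0.05 * seq_len(6) / 6
  passed <- which(sort(tab$p) <= thresh)
  reject <- if (length(passed)) ord[seq_len(max(passed))] else integer(0)
  expect_setequal(which(tab$significant), reject)
  expect_true(all(tab$significant[1:2]))
  ## duplicated groups: exact null, zero discoveries
  dup <- rbind(vals[1:20, ], vals[1:20, ])
  tab0 <- compare_groups_fdr(dup, labels, q = 0.05)
  expect_false(any(tab0$significant))
  ## constant metric skipped with a note
  tabc <- compare_groups_fdr(cbind(vals, konst = rep(1, 40)), labels)
  expect_true(is.na(tabc$p[7]))
  expect_match(run_log(tabc), "constant")
})

test_that("patient graphs lose motor degree and gain path length by construction", {
  ## single-cohort version of the direction check (full 20-seed majority in
  ## the acceptance suite)
  co <- preprocess_cohort(generate_cohort(desk_cohort_spec("network", seed = 42)))
  res <- network_group_analysis(co, alpha = 0.35)
  deg <- res$local[res$local$family == "degree", ]
  pl <- res$local[res$local$family == "path_length", ]
  expect_lt(mean(deg$mean_patient - deg$mean_control), 0)
  expect_gt(mean(pl$mean_patient - pl$mean_control), 0)
  expect_gt(res$global$mean_patient[1], res$global$mean_control[1])
})
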