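test_that("K follows the min(cap, n-1) rule", {
  set.seed(1)
  co <- matrix(rnorm(800 * 2), 800, 2, dimnames = list(paste0("c", 1:800), NULL))
  expect_equal(build_knn(co, K_cap = 750L)$K, 750L)
  expect_equal(build_knn(co[1:100, ], K_cap = 750L)$K, 99L)
  expect_error(build_knn(co[1, , drop = FALSE]), class = "isrmap_input_error")
})

test_that("KNN equals the brute-force all-pairs sort", {
  set.seed(42)
  co <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(paste0("c", 1:20), NULL))
  knn <- build_knn(co, K_cap = 6L)
  bf <- oracle_knn(co, 6L)
  for (i in 1:20) expect_setequal(knn$neighbors[i, ], bf[i, ])
})

test_that("SNN Jaccard graph matches brute-force pairwise computation", {
  set.seed(7)
  co <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(paste0("c", 1:50), NULL))
  knn <- build_knn(co, K_cap = 10L)
  snn <- build_snn_jaccard(knn, prune_cutoff = 1 / 15)
  expect_equal(as.matrix(snn$adjacency), oracle_snn(knn$neighbors, 1 / 15),
               tolerance = 1e-12, ignore_attr = TRUE)
  # symmetry, no self-edges, all weights at or above the cutoff
  expect_true(Matrix::isSymmetric(snn$adjacency))
  expect_equal(sum(Matrix::diag(snn$adjacency)), 0)
  expect_true(all(snn$adjacency@x >= 1 / 15))
})

test_that("SNN edge cases: mutual pairs and disjoint sets", {
  co <- matrix(c(0, 0.1, 10, 10.1, 0, 0, 0, 0), 4, 2,
               dimnames = list(paste0("c", 1:4), NULL))
  knn <- build_knn(co, K_cap = 1L)
  snn <- build_snn_jaccard(knn)
  # two tight pairs: within-pair sets identical -> weight 1; across -> none
  expect_equal(snn$adjacency[1, 2], 1)
  expect_equal(snn$adjacency[3, 4], 1)
  expect_equal(snn$adjacency[1, 3] + snn$adjacency[1, 4] + snn$adjacency[2, 3], 0)
})

test_that("Louvain recovers disconnected cliques and handles singletons", {
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  snn <- snn_from_adj(adj)
  p <- louvain(snn, resolution = 1, seed = 1)
  expect_equal(p$n_communities, 2L)
  expect_equal(p$membership[1:3], rep(p$membership[1], 3))
  expect_equal(p$membership[4:6], rep(p$membership[4], 3))
  expect_equal(p$modularity, oracle_modularity(adj, p$membership, 1),
               tolerance = 1e-12)

  one <- snn_from_adj(matrix(0, 1, 1))
  p1 <- louvain(one, resolution = 1, seed = 1)
  expect_equal(p1$n_communities, 1L)
  expect_equal(p1$modularity, 0)
})

test_that("Louvain attains the enumeration optimum on small graphs", {
  set.seed(5)
  for (rep in 1:4) {
    n <- sample(5:8, 1)
    adj <- random_graph_adj(n)
    if (sum(adj) == 0) next
    snn <- snn_from_adj(adj)
    for (r in c(0.5, 1)) {
      best_q <- max(vapply(oracle_partitions(n), function(mem)
        oracle_modularity(adj, mem, r), numeric(1)))
      got_q <- max(vapply(1:10, function(s)
        louvain(snn, resolution = r, seed = s)$modularity, numeric(1)))
      expect_equal(got_q, best_q, tolerance = 1e-9)
    }
  }
})

test_that("partition metric reproduces its hand-computed values", {
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1; diag(adj) <- 0
  snn <- snn_from_adj(adj)
  expect_equal(partition_metric(snn, c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(partition_metric(snn, 0:5), 0.5)
  # complete weight-1 graph as a single community
  full <- matrix(1, 5, 5); diag(full) <- 0
  expect_equal(partition_metric(snn_from_adj(full), rep(0L, 5)), 1.0)
  expect_true(partition_metric(snn, c(0, 0, 1, 1, 2, 2)) <= 1)
})

test_that("resolution search uses the documented grid and finds cliques", {
  grid <- seq(0.05, 1.225, by = 0.025)
  expect_length(grid, 48L)
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
  snn <- snn_from_adj(adj)
  scan <- resolution_search(snn, seed = 1)
  expect_identical(scan$grid, grid)
  expect_equal(max(scan$metric), 1.0)
  expect_equal(scan$metric[scan$selected], max(scan$metric))
  expect_equal(scan$partition$n_communities, 2L)
  # ties resolve to the smallest resolution
  expect_equal(scan$resolution, scan$grid[which.max(scan$metric)])
  expect_error(resolution_search(snn, grid = c(0.5, 0.2)),
               class = "isrmap_config_error")
})

# three leaf types; types 1 and 2 share a strong "super-type" program so a
# coarse seed partition must be broken apart, while pure leaves must not split
hier_sim <- function(seed = 13) {
  with_seed(seed, {
    ng <- 600L; per <- 60L
    base <- rlnorm(ng, 0, 1)
    super_idx <- 1:40; subA <- 41:70; subB <- 71:100; solo_idx <- 101:140
    progs <- list()
    p1 <- base; p1[super_idx] <- p1[super_idx] * 8; p1[subA] <- p1[subA] * 3
    p2 <- base; p2[super_idx] <- p2[super_idx] * 8; p2[subB] <- p2[subB] * 3
    p3 <- base; p3[solo_idx] <- p3[solo_idx] * 8
    progs <- list(p1, p2, p3)
    counts <- matrix(0L, ng, 3L * per)
    for (t in 1:3) {
      pr <- progs[[t]] / sum(progs[[t]])
      for (c in seq_len(per)) {
        counts[, (t - 1L) * per + c] <- as.vector(rmultinom(1, 2500, pr))
      }
    }
    dimnames(counts) <- list(sprintf("g%03d", seq_len(ng)),
                             sprintf("b%03d", seq_len(ncol(counts))))
    list(counts = as(counts, "CsparseMatrix"),
         type = rep(c("A1", "A2", "B"), each = per))
  })
}

test_that("iterative sub-clustering splits planted hierarchy to its leaves", {
  hs <- hier_sim()
  norm <- normalize_counts(hs$counts)
  cfg <- pipeline_config(k_cap = 30L, n_pcs = 15L, log_level = "warn")
  vg <- select_variable_genes(norm, n_bins = cfg$vg_bins,
                              z_cutoff = cfg$vg_z_cutoff,
                              mean_bounds = cfg$vg_mean_bounds)
  emb <- compute_pca(norm, vg, n_pcs = cfg$n_pcs)
  snn <- build_snn_jaccard(build_knn(emb, cfg$k_cap), cfg$prune_cutoff)
  # seed partition merges the two sub-types of the super-type
  seed_part <- ifelse(hs$type == "B", 1L, 0L)
  cl <- iterative_subcluster(norm, seed_part, snn, cfg)
  expect_equal(length(unique(cl$cluster)), 3L)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, hs$type), 1.0)
  # the merged super-type leaf was split: its labels gained a dot level
  expect_true(any(grepl(".", cl$path, fixed = TRUE)))
  # determinism
  cl2 <- iterative_subcluster(norm, seed_part, snn, cfg)
  expect_identical(cl$path, cl2$path)
})

test_that("a homogeneous cluster never splits", {
  with_seed(3, {
    ng <- 400L
    base <- rlnorm(ng, 0, 1)
    counts <- vapply(1:80, function(i) as.vector(rmultinom(1, 2000, base / sum(base))),
                     numeric(ng))
    dimnames(counts) <- list(sprintf("g%03d", 1:ng), sprintf("b%02d", 1:80))
    norm <- normalize_counts(as(counts, "CsparseMatrix"))
    cfg <- pipeline_config(k_cap = 30L, n_pcs = 10L, log_level = "warn")
    emb <- compute_pca(norm, select_variable_genes(norm, n_bins = 10L), 10L)
    snn <- build_snn_jaccard(build_knn(emb, cfg$k_cap), cfg$prune_cutoff)
    cl <- iterative_subcluster(norm, rep(0L, 80), snn, cfg)
    expect_equal(unique(cl$cluster), 1L)
    expect_false(any(grepl(".", cl$path, fixed = TRUE)))
  })
})

test_that("returned Louvain modularity dominates trivial partitions", {
  set.seed(9)
  adj <- random_graph_adj(8, 0.6)
  snn <- snn_from_adj(adj)
  for (r in c(0.3, 1)) {
    p <- louvain(snn, resolution = r, seed = 2)
    q_single <- oracle_modularity(adj, rep(0L, 8), r)
    q_singletons <- oracle_modularity(adj, 0:7, r)
    expect_gte(p$modularity + 1e-12, max(q_single, q_singletons))
  }
})
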