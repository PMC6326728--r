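# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (loops, enumeration, closed forms) and
# never call the implementation paths they check.

# all-pairs KNN by explicit sort; ties toward the lower index
oracle_knn <- function(coords, K) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    ord <- ord[ord != i]
    c(i, ord[seq_len(K)])
  }, integer(K + 1L)))
}

# pairwise Jaccard over neighbor sets, dense loop
oracle_snn <- function(neighbors, prune_cutoff) {
  n <- nrow(neighbors)
  adj <- matrix(0, n, n)
  sets <- lapply(seq_len(n), function(i) neighbors[i, ])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      if (inter == 0L) next
      jac <- inter / length(union(sets[[i]], sets[[j]]))
      if (jac >= prune_cutoff) adj[i, j] <- adj[j, i] <- jac
    }
  }
  adj
}

# all set partitions of 1..n as membership vectors (restricted growth)
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(mem, k) {
    i <- length(mem) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- mem
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) rec(c(mem, lab), max(k, lab))
  }
  rec(integer(0), 0L)
  out
}

# resolution-scaled modularity from its definition
oracle_modularity <- function(adj, mem, resolution) {
  w_tot <- sum(adj) / 2
  if (w_tot == 0) return(0)
  q <- 0
  for (c in unique(mem)) {
    inside <- mem == c
    w_in <- sum(adj[inside, inside]) / 2
    s_c <- sum(adj[inside, ])
    q <- q + w_in / w_tot - resolution * (s_c / (2 * w_tot))^2
  }
  q
}

# enrichment score from the definition: explicit running sum walk
oracle_es <- function(stats, set, p = 1) {
  hit <- names(stats) %in% set
  k <- sum(hit)
  n <- length(stats)
  w <- unname(abs(stats)^p)
  denom <- sum(w[hit])
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (denom > 0) w[i] / denom else 1 / k
    } else {
      -1 / (n - k)
    }
    if (abs(run) > abs(best) || (abs(run) == abs(best) && run > best)) best <- run
  }
  best
}

# symmetric weighted adjacency of a random graph (for Louvain oracles)
random_graph_adj <- function(n, p_edge = 0.5) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- round(runif(1, 0.1, 1), 3)
    }
  }
  adj
}

snn_from_adj <- function(adj) {
  ids <- paste0("c", seq_len(nrow(adj)))
  dimnames(adj) <- list(ids, ids)
  structure(list(ids = ids,
                 adjacency = as(adj, "CsparseMatrix"),
                 K = NA_integer_, prune_cutoff = 0),
            class = "snn_graph")
}

# small droplet simulation shared by integration-style unit tests
small_sim <- function(seed = 7, ...) {
  cell_sim_config(n_cell_types = 4L, cells_per_type = 150L, n_genes = 2000L,
                  markers_per_type = 40L, n_empty_droplets = 3000L,
                  seed = seed, ...)
}

# reduced pipeline config matched to small_sim problem sizes
small_config <- function(...) {
  pipeline_config(k_cap = 100L, n_pcs = 30L, n_perm = 200L,
                  log_level = "warn", ...)
}
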