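#' K-nearest-neighbor sets in PC space
#'
#' K is capped at `min(K_cap, n_cells - 1)`. The neighbor set of a cell is
#' itself plus its K nearest cells by Euclidean distance in the embedding;
#' distance ties are broken toward the lower cell index. Including the cell
#' itself makes the two-cell case well defined and follows common SNN
#' practice.
#'
#' @param embedding a [compute_pca()] result, or a cells x dims coordinate
#'   matrix with rownames.
#' @param K_cap upper bound on K (default 750).
#' @return object of class `knn_sets`: list with `ids` and `neighbors`, an
#'   n x (K+1) integer matrix of neighbor indices (first column = self).
#' @export
build_knn <- function(embedding, K_cap = 750L) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coordinates else embedding
  n <- nrow(coords)
  if (n < 2L) isr_stop("need >= 2 cells for KNN", "isrmap_input_error")
  K <- min(K_cap, n - 1L)
  sq <- rowSums(coords^2)
  nb <- matrix(0L, n, K + 1L)
  # squared distances block-wise to bound memory
  block <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(n, s + block - 1L)
    d2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    for (r in seq_along(rows)) {
      i <- rows[r]
      d <- d2[r, ]
      d[i] <- -Inf                      # self always first
      ord <- order(d)                   # stable: ties -> lower index
      nb[i, ] <- c(i, ord[ord != i][seq_len(K)])
    }
  }
  structure(list(ids = rownames(coords), neighbors = nb, K = K),
            class = "knn_sets")
}

#' Shared-nearest-neighbor graph with Jaccard weights
#'
#' For every pair of cells sharing at least one neighbor, the edge weight is
#' the Jaccard index of their neighbor sets; edges with weight below
#' `prune_cutoff` (default 1/15) are removed, as are self-edges.
#'
#' @param knn a [build_knn()] result.
#' @param prune_cutoff minimum retained Jaccard similarity (default 1/15).
#' @return object of class `snn_graph`: list with `ids`, `adjacency`
#'   (symmetric sparse weight matrix, zero diagonal), `K`, `prune_cutoff`.
#' @export
build_snn_jaccard <- function(knn, prune_cutoff = 1 / 15) {
  nb <- knn$neighbors
  n <- nrow(nb)
  size <- ncol(nb)  # all sets have K + 1 members
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), size), j = as.vector(nb),
                            x = 1, dims = c(n, n))
  # intersection counts block-by-block, pruning each block right away so
  # the unpruned matrix is never held in full
  block <- max(64L, min(n, as.integer(2e7 / max(n, 1L))))
  parts <- vector("list", ceiling(n / block))
  bi <- 0L
  for (s in seq(1L, n, by = block)) {
    rows <- s:min(n, s + block - 1L)
    inter <- Matrix::tcrossprod(A[rows, , drop = FALSE], A)
    inter <- as(as(inter, "CsparseMatrix"), "generalMatrix")
    inter@x <- inter@x / (2 * size - inter@x)  # Jaccard = I/(|A|+|B|-I)
    inter@x[inter@x < prune_cutoff] <- 0
    inter <- Matrix::drop0(inter)
    tr <- Matrix::mat2triplet(inter)
    keep <- tr$i + s - 1L != tr$j             # no self-edges
    bi <- bi + 1L
    parts[[bi]] <- list(i = tr$i[keep] + s - 1L, j = tr$j[keep], x = tr$x[keep])
  }
  adjacency <- Matrix::sparseMatrix(
    i = unlist(lapply(parts, `[[`, "i")),
    j = unlist(lapply(parts, `[[`, "j")),
    x = unlist(lapply(parts, `[[`, "x")),
    dims = c(n, n), dimnames = list(knn$ids, knn$ids))
  structure(list(ids = knn$ids, adjacency = adjacency, K = knn$K,
                 prune_cutoff = prune_cutoff),
            class = "snn_graph")
}

# resolution-scaled modularity of a membership vector on a symmetric
# adjacency: Q(r) = sum_c [ W_in(c)/W - r (S_c/(2W))^2 ]
modularity_value <- function(adj, mem, resolution) {
  w_tot <- sum(adj) / 2
  if (w_tot == 0) return(0)
  labs <- sort(unique(mem))
  M <- Matrix::sparseMatrix(i = seq_along(mem), j = match(mem, labs), x = 1,
                            dims = c(length(mem), length(labs)))
  cw <- as.matrix(Matrix::t(M) %*% adj %*% M)
  sum(diag(cw) / 2 / w_tot - resolution * (rowSums(cw) / (2 * w_tot))^2)
}

#' Louvain community detection at a given resolution
#'
#' Greedy modularity optimization (local moving + graph aggregation,
#' repeated to a fixed point) of the resolution-scaled modularity
#' \deqn{Q(r) = \sum_c [W_{in}(c)/W - r \, (S_c/(2W))^2]}
#' with \eqn{W} the total edge weight, \eqn{W_{in}(c)} the internal weight
#' and \eqn{S_c} the summed weighted degree of community `c`. Implemented
#' in compiled code; the node sweep order is shuffled under `seed`. Graphs
#' without edges yield all-singleton partitions with Q = 0.
#'
#' @param snn an `snn_graph`, or a symmetric sparse adjacency matrix.
#' @param resolution resolution parameter r (> 0).
#' @param seed RNG seed for the sweep order.
#' @return object of class `snn_partition`: list with `membership`
#'   (integer labels, contiguous from 0, in order of first appearance),
#'   `resolution`, `modularity`, `n_communities`.
#' @export
louvain <- function(snn, resolution = 1, seed = 1L) {
  adj <- if (inherits(snn, "snn_graph")) snn$adjacency else snn
  adj <- as(as(adj, "CsparseMatrix"), "generalMatrix")
  n <- nrow(adj)
  if (n == 0L) isr_stop("empty graph", "isrmap_input_error")
  if (length(adj@x) == 0L) {
    mem <- seq_len(n) - 1L
    return(structure(list(membership = mem, resolution = resolution,
                          modularity = 0, n_communities = n),
                     class = "snn_partition"))
  }
  mem <- with_seed(seed,
    .louvain_cpp(adj@p, adj@i, adj@x, n, resolution))
  mem <- match(mem, unique(mem)) - 1L  # contiguous from 0, first-appearance order
  q <- modularity_value(adj, mem, resolution)
  structure(list(membership = mem, resolution = resolution, modularity = q,
                 n_communities = length(unique(mem))),
            class = "snn_partition")
}

#' Mean unifiability/isolability partition quality
#'
#' Per community `c`: unifiability is the weighted internal edge density
#' `W_in(c) / (|c| (|c|-1) / 2)` (1 for singletons; Jaccard weights <= 1
#' bound it by 1), and isolability is `1 - W_cut(c) / (W_in(c) + W_cut(c))`
#' (1 when the community has no incident edges). The metric is the mean over
#' communities of the average of the two, and lies in [0, 1]; it penalizes
#' both over-merging (low density) and over-splitting (low isolability).
#'
#' @param snn an `snn_graph`.
#' @param partition an `snn_partition`, or an integer membership vector.
#' @return metric value in [0, 1].
#' @export
partition_metric <- function(snn, partition) {
  mem <- if (inherits(partition, "snn_partition")) partition$membership else partition
  adj <- snn$adjacency
  n <- nrow(adj)
  labs <- sort(unique(mem))
  M <- Matrix::sparseMatrix(i = seq_len(n), j = match(mem, labs), x = 1,
                            dims = c(n, length(labs)))
  cw <- as.matrix(Matrix::t(M) %*% adj %*% M)  # community-pair weight sums
  w_in <- diag(cw) / 2
  w_cut <- rowSums(cw) - diag(cw)
  sizes <- as.vector(Matrix::colSums(M))
  unif <- ifelse(sizes >= 2, w_in / (sizes * (sizes - 1) / 2), 1)
  inc <- w_in + w_cut
  isol <- ifelse(inc > 0, 1 - w_cut / inc, 1)
  mean((unif + isol) / 2)
}

#' Louvain resolution search
#'
#' Runs [louvain()] at every grid resolution, scores each partition with
#' [partition_metric()], and selects the resolution attaining the maximum
#' metric (ties toward the smallest resolution). The default grid covers
#' 0.05 to 1.225 in steps of 0.025 (48 points).
#'
#' @param snn an `snn_graph`.
#' @param grid strictly increasing resolutions (default
#'   `seq(0.05, 1.225, by = 0.025)`).
#' @param seed base RNG seed; run k uses `seed + k - 1`.
#' @return object of class `resolution_scan`: list with `grid`, `metric`
#'   (per resolution), `partitions` (list of `snn_partition`), `selected`
#'   (index into the grid), `resolution` and `partition` (the winners).
#' @export
resolution_search <- function(snn, grid = seq(0.05, 1.225, by = 0.025),
                              seed = 1L) {
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    isr_stop("resolution grid must be nonempty and strictly increasing",
             "isrmap_config_error")
  partitions <- vector("list", length(grid))
  metric <- numeric(length(grid))
  for (k in seq_along(grid)) {
    p <- louvain(snn, resolution = grid[k], seed = seed + k - 1L)
    partitions[[k]] <- p
    metric[k] <- partition_metric(snn, p)
  }
  sel <- which.max(metric)  # first max = smallest resolution on ties
  isr_log("debug", sprintf("resolution search: selected r=%.3f (metric %.4f, %d communities)",
                           grid[sel], metric[sel], partitions[[sel]]$n_communities))
  structure(list(grid = grid, metric = metric, partitions = partitions,
                 selected = sel, resolution = grid[sel],
                 partition = partitions[[sel]]),
            class = "resolution_scan")
}

# metric contribution of a set of nodes, viewed as communities of `labels`
# within the graph `adj` restricted to `cells`: mean over the labelled
# communities of (unifiability + isolability)/2
community_contribution <- function(adj, cells, labels) {
  sub <- adj[cells, cells, drop = FALSE]
  labs <- sort(unique(labels))
  vals <- vapply(labs, function(l) {
    inside <- labels == l
    w_in <- sum(sub[inside, inside]) / 2
    w_cut <- sum(sub[inside, !inside])
    nc <- sum(inside)
    unif <- if (nc >= 2) w_in / (nc * (nc - 1) / 2) else 1
    inc <- w_in + w_cut
    isol <- if (inc > 0) 1 - w_cut / inc else 1
    (unif + isol) / 2
  }, numeric(1))
  mean(vals)
}

#' Iterative sub-clustering to convergence
#'
#' Starting from a top-level partition (typically the [resolution_search()]
#' winner on all cells), each leaf cluster with at least `min_cells` cells
#' is re-analyzed on its own: variable-gene selection, PCA, SNN graph and
#' resolution search are re-run on that cluster's cells alone. A proposed
#' split is accepted when it has >= 2 communities of size >= `min_cells`
#' each and does not decrease the cluster's metric contribution in the
#' graph it was found in (the parent graph). Convergence is reached when no
#' leaf splits; leaves are processed in ascending label order.
#'
#' @param normalized genes x barcodes normalized matrix (all cells).
#' @param top either a `resolution_scan`/`snn_partition` for all cells or an
#'   integer membership vector.
#' @param snn the SNN graph the top-level partition was found in (recorded
#'   for provenance; the split test itself is evaluated on each cluster's
#'   own sub-graph).
#' @param config a [pipeline_config()] (controls variable-gene, PCA, KNN,
#'   pruning, grid, `min_cells` and seed parameters).
#' @return object of class `cluster_assignment`: data.frame with columns
#'   `barcode`, `path` (hierarchical dot label, e.g. `"3.1"`), `cluster`
#'   (final leaf label, contiguous integers from 1 in path order).
#' @export
iterative_subcluster <- function(normalized, top, snn,
                                 config = pipeline_config()) {
  if (inherits(top, "resolution_scan")) top <- top$partition
  mem <- if (inherits(top, "snn_partition")) top$membership else top
  barcodes <- colnames(normalized)
  paths <- as.character(mem + 1L)

  # leaves queued for examination, ascending label order
  queue <- sort(unique(paths))

  while (length(queue)) {
    label <- queue[[1]]
    queue <- queue[-1]
    cells <- which(paths == label)
    if (length(cells) < 2L * config$min_cells) next
    split <- try_split(normalized[, cells, drop = FALSE], config)
    if (is.null(split)) next
    sizes <- tabulate(split$partition$membership + 1L)
    if (length(sizes) < 2L || any(sizes < config$min_cells)) next
    # accept only if the split raises the metric contribution on the graph
    # it was found in, relative to keeping the leaf whole
    sub_adj <- split$snn$adjacency
    before <- community_contribution(sub_adj, seq_len(length(cells)),
                                     rep(1L, length(cells)))
    after <- community_contribution(sub_adj, seq_len(length(cells)),
                                    split$partition$membership)
    if (after < before) next
    kids <- paste0(label, ".", split$partition$membership + 1L)
    paths[cells] <- kids
    queue <- sort(unique(c(queue, unique(kids))))
    isr_log("debug", sprintf("cluster %s split into %d sub-clusters", label,
                             length(sizes)))
  }

  leaf_order <- sort(unique(paths))
  structure(data.frame(barcode = barcodes, path = paths,
                       cluster = match(paths, leaf_order),
                       stringsAsFactors = FALSE),
            class = c("cluster_assignment", "data.frame"))
}

# re-run the embed + cluster stack on one cluster's cells; NULL means the
# cluster cannot be broken down
try_split <- function(sub_norm, config) {
  out <- tryCatch({
    genes <- select_variable_genes(sub_norm, n_bins = config$vg_bins,
                                   z_cutoff = config$vg_z_cutoff,
                                   mean_bounds = config$vg_mean_bounds)
    emb <- compute_pca(sub_norm, genes, n_pcs = config$n_pcs)
    knn <- build_knn(emb, K_cap = config$k_cap)
    sub_snn <- build_snn_jaccard(knn, prune_cutoff = config$prune_cutoff)
    scan <- resolution_search(sub_snn, grid = config$resolution_grid,
                              seed = config$seed)
    list(partition = scan$partition, snn = sub_snn)
  }, isrmap_error = function(e) NULL)
  if (!is.null(out) && out$partition$n_communities < 2L) out <- NULL
  out
}
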