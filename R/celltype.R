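#' Marker-based cell-type probabilities of one cluster
#'
#' For each candidate cell type, each of its marker genes that is expressed
#' in the cluster (detected above `min_detect_frac` of the cluster's cells;
#' default: at least one cell) contributes a gene score equal to its mean
#' normalized expression over all cells of the cluster multiplied by the
#' fraction of the cluster's cells it is detected in. The type's raw score
#' is the sum of gene scores divided by the type's total number of markers
#' (expressed or not), which guards against ascertainment bias from
#' unequally sized marker panels. Raw scores are rescaled to sum to one and
#' hence reflect probabilities; the cluster is assigned the type whose
#' probability strictly exceeds `threshold`, otherwise it is `UNASSIGNED`.
#'
#' @param normalized genes x barcodes normalized matrix.
#' @param cells column indices or barcode ids of the cluster's cells.
#' @param marker_ref named list mapping cell-type name to marker gene ids.
#' @param threshold assignment probability threshold (default 0.5, strict).
#' @param min_detect_frac minimum detection fraction for a marker to count
#'   as expressed in the cluster (default 0: any detected cell).
#' @return object of class `celltype_probs`: list with `scores`
#'   (data.frame: `cell_type`, `raw_score`, `probability`), `assignment`
#'   (type name or `"UNASSIGNED"`), `threshold`.
#' @examples
#' norm <- Matrix::Matrix(0, 3, 4, sparse = TRUE,
#'                        dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:4)))
#' norm["g1", 1:2] <- 4; norm["g3", ] <- 1
#' ref <- list(T1 = c("g1", "g2"), T2 = "g3")
#' score_cluster(norm, 1:4, ref)  # probabilities 1/3 and 2/3, assigned T2
#' @export
score_cluster <- function(normalized, cells, marker_ref, threshold = 0.5,
                          min_detect_frac = 0) {
  marker_ref <- validate_marker_reference(marker_ref)
  cells <- resolve_cells(cells, colnames(normalized))
  if (!length(cells)) isr_stop("empty cluster", "isrmap_input_error")
  universe <- rownames(normalized)
  if (!any(unlist(marker_ref) %in% universe))
    isr_stop("no marker of any cell type is present in the gene universe",
             "isrmap_input_error")
  sub <- normalized[, cells, drop = FALSE]
  raw <- vapply(marker_ref, function(markers) {
    present <- intersect(markers, universe)
    if (!length(present)) return(0)
    m <- sub[present, , drop = FALSE]
    mu <- Matrix::rowSums(m) / length(cells)
    frac <- Matrix::rowSums(m > 0) / length(cells)
    expressed <- frac > min_detect_frac
    sum(mu[expressed] * frac[expressed]) / length(markers)
  }, numeric(1))
  prob <- if (sum(raw) > 0) raw / sum(raw) else rep(NA_real_, length(raw))
  assignment <- "UNASSIGNED"
  if (sum(raw) > 0 && max(prob) > threshold) {
    assignment <- names(marker_ref)[which.max(prob)]
  }
  structure(list(scores = data.frame(cell_type = names(marker_ref),
                                     raw_score = unname(raw),
                                     probability = unname(prob),
                                     stringsAsFactors = FALSE),
                 assignment = assignment, threshold = threshold),
            class = "celltype_probs")
}

#' Cell-type assignment of every cluster
#'
#' Applies [score_cluster()] to each final leaf cluster of an assignment.
#'
#' @inheritParams score_cluster
#' @param assignment a `cluster_assignment` or label vector aligned with the
#'   matrix columns.
#' @return data.frame with one row per (cluster, cell type): columns
#'   `cluster`, `cell_type`, `raw_score`, `probability`, `assignment` (the
#'   cluster's call, repeated across its rows).
#' @export
assign_all <- function(normalized, assignment, marker_ref, threshold = 0.5,
                       min_detect_frac = 0) {
  labels <- assignment_labels(assignment, colnames(normalized))
  out <- lapply(sort(unique(labels)), function(cl) {
    r <- score_cluster(normalized, which(labels == cl), marker_ref,
                       threshold = threshold,
                       min_detect_frac = min_detect_frac)
    cbind(cluster = cl, r$scores, assignment = r$assignment,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-row-per-cluster summary of [assign_all()]
#' @param prob_table result of [assign_all()].
#' @return data.frame with `cluster`, `assignment`, `top_probability`.
#' @export
celltype_calls <- function(prob_table) {
  out <- lapply(split(prob_table, prob_table$cluster), function(d) {
    data.frame(cluster = d$cluster[1], assignment = d$assignment[1],
               top_probability = if (all(is.na(d$probability))) NA_real_
                                 else max(d$probability, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
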