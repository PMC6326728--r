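# Vectorized core of the bimodal LRT. Per gene and group the model is:
# a value is exactly 0 with probability 1 - pi, and Gaussian(mu, sigma)
# otherwise (fitted on the positive observations, sigma floored). The test
# compares separate models per group against a pooled model: 3 df when both
# groups have >= 2 positive observations, otherwise the Gaussian part is
# dropped for both groups and the LRT is 1 df on the detection rate alone.
# Inputs are per-gene sufficient statistics: n (group size), n1 (positive
# count), s1/s2 (sum and sum of squares of positives).
bimod_core <- function(nA, n1A, s1A, s2A, nB, n1B, s1B, s2B, sigma_min = 1e-3) {
  bern <- function(n, n1) {
    p <- n1 / n
    term <- function(k, q) ifelse(k > 0, k * log(q), 0)
    term(n1, p) + term(n - n1, 1 - p)
  }
  gauss <- function(n1, s1, s2) {
    mu <- ifelse(n1 > 0, s1 / n1, 0)
    v <- pmax(ifelse(n1 > 0, s2 / n1 - mu^2, 0), sigma_min^2)
    ifelse(n1 >= 2, -n1 / 2 * (log(2 * pi * v) + (s2 / n1 - mu^2) / v), 0)
  }
  full_ok <- n1A >= 2 & n1B >= 2
  ll_sep <- bern(nA, n1A) + bern(nB, n1B) +
    ifelse(full_ok, gauss(n1A, s1A, s2A) + gauss(n1B, s1B, s2B), 0)
  ll_pool <- bern(nA + nB, n1A + n1B) +
    ifelse(full_ok, gauss(n1A + n1B, s1A + s1B, s2A + s2B), 0)
  stat <- pmax(0, 2 * (ll_sep - ll_pool))
  df <- ifelse(full_ok, 3, 1)
  list(stat = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE),
       log_p = pchisq(stat, df, lower.tail = FALSE, log.p = TRUE),
       mean_A = s1A / nA, mean_B = s1B / nB,
       det_A = n1A / nA, det_B = n1B / nB)
}

#' Bimodal likelihood-ratio test for one gene
#'
#' Tests whether two groups of normalized log-expression values were drawn
#' from one bimodal (zero-inflated Gaussian) distribution or two. Each
#' group's model puts mass `1 - pi` on exact zeros and a Gaussian on the
#' positive values; the LRT compares per-group fits against a pooled fit
#' (3 df). When either group has fewer than 2 positive values the Gaussian
#' component is dropped for both groups and the test reduces to a 1-df LRT
#' on the detection rate.
#'
#' @param values_a,values_b numeric vectors of normalized log expression
#'   (zeros meaningful); both nonempty.
#' @param sigma_min floor on the fitted Gaussian sd (default 1e-3).
#' @return list with `lrt_stat`, `df`, `p_value`, `direction`
#'   (sign of `mean(values_a) - mean(values_b)`), group means and detection
#'   fractions.
#' @export
bimod_lrt <- function(values_a, values_b, sigma_min = 1e-3) {
  if (!length(values_a) || !length(values_b))
    isr_stop("both groups must be nonempty", "isrmap_input_error")
  pa <- values_a[values_a > 0]; pb <- values_b[values_b > 0]
  r <- bimod_core(length(values_a), length(pa), sum(pa), sum(pa^2),
                  length(values_b), length(pb), sum(pb), sum(pb^2),
                  sigma_min = sigma_min)
  list(lrt_stat = r$stat, df = r$df, p_value = r$p,
       direction = sign(r$mean_A - r$mean_B),
       mean_a = r$mean_A, mean_b = r$mean_B,
       detect_a = r$det_A, detect_b = r$det_B)
}

# per-gene sufficient statistics of a cell subset of a sparse normalized
# matrix
group_stats <- function(normalized, cells) {
  sub <- normalized[, cells, drop = FALSE]
  list(n = length(cells),
       n1 = Matrix::rowSums(sub > 0),
       s1 = Matrix::rowSums(sub),
       s2 = Matrix::rowSums(sub^2))
}

# vectorized bimod LRT of cell set A vs B over all genes
bimod_lrt_all <- function(normalized, cells_a, cells_b, sigma_min = 1e-3) {
  a <- group_stats(normalized, cells_a)
  b <- group_stats(normalized, cells_b)
  r <- bimod_core(a$n, a$n1, a$s1, a$s2, b$n, b$n1, b$s1, b$s2,
                  sigma_min = sigma_min)
  r$gene <- rownames(normalized)
  r
}

#' Marker genes of one cluster
#'
#' Runs the bimodal LRT of the cluster's cells against all other cells for
#' every gene detected in at least `min_frac` of either group, adjusts
#' p-values over the tested genes, and flags as markers the genes with
#' adjusted p below `alpha` and higher mean in the cluster.
#'
#' @param normalized genes x barcodes normalized matrix.
#' @param assignment a `cluster_assignment` (from
#'   [iterative_subcluster()]) or a vector of cluster labels aligned with
#'   the matrix columns.
#' @param cluster the cluster label to test.
#' @param min_frac detection-fraction prefilter (default 0.1).
#' @param alpha marker significance level on the adjusted p (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param sigma_min see [bimod_lrt()].
#' @return data.frame (one row per tested gene) with test results, adjusted
#'   p-values and a logical `is_marker` column, ordered by adjusted then raw
#'   p-value.
#' @export
markers_for_cluster <- function(normalized, assignment, cluster,
                                min_frac = 0.1, alpha = 0.05,
                                adjust = c("bonferroni", "BH"),
                                sigma_min = 1e-3) {
  adjust <- match.arg(adjust)
  labels <- assignment_labels(assignment, colnames(normalized))
  if (length(unique(labels)) < 2L)
    isr_stop("need >= 2 clusters to call markers", "isrmap_input_error")
  cells_a <- which(labels == cluster)
  if (!length(cells_a)) isr_stop("unknown cluster label", "isrmap_input_error")
  if (length(cells_a) == ncol(normalized))
    isr_stop("cluster covers all cells; nothing to compare against",
             "isrmap_input_error")
  cells_b <- setdiff(seq_len(ncol(normalized)), cells_a)
  r <- bimod_lrt_all(normalized, cells_a, cells_b, sigma_min = sigma_min)
  keep <- r$det_A >= min_frac | r$det_B >= min_frac
  adj <- p.adjust(r$p[keep], method = if (adjust == "BH") "BH" else "bonferroni")
  out <- data.frame(gene = r$gene[keep], lrt_stat = r$stat[keep],
                    df = r$df[keep], p_value = r$p[keep], adjusted_p = adj,
                    mean_cluster = r$mean_A[keep], mean_rest = r$mean_B[keep],
                    detect_cluster = r$det_A[keep], detect_rest = r$det_B[keep],
                    stringsAsFactors = FALSE)
  out$is_marker <- out$adjusted_p < alpha & out$mean_cluster > out$mean_rest
  out[order(out$adjusted_p, out$p_value, out$gene), ]
}

assignment_labels <- function(assignment, barcodes) {
  if (inherits(assignment, "cluster_assignment") || is.data.frame(assignment)) {
    labels <- assignment$cluster[match(barcodes, assignment$barcode)]
    if (anyNA(labels)) isr_stop("cluster assignment does not cover all barcodes",
                                "isrmap_input_error")
    labels
  } else {
    if (length(assignment) != length(barcodes))
      isr_stop("cluster labels do not align with matrix columns",
               "isrmap_input_error")
    assignment
  }
}

#' Ranked gene list from a two-group contrast
#'
#' Per gene, the ranking statistic is `direction * (-log10 p)` from the
#' bimodal LRT of cell set A against cell set B; genes are returned in
#' descending order of the statistic, with ties broken by LRT statistic and
#' then gene id. By default only genes detected in at least one cell of
#' either group are ranked.
#'
#' @param normalized genes x barcodes normalized matrix.
#' @param cells_a,cells_b column indices (or barcode ids) of the two groups.
#' @param descriptor free-text contrast label stored on the result.
#' @param min_cells_detect minimum cells (across both groups) a gene must be
#'   detected in to be ranked (default 1).
#' @param sigma_min see [bimod_lrt()].
#' @return data.frame of class `ranked_list` with columns `gene`, `stat`,
#'   `lrt_stat`, `p_value`, `direction`, ordered by decreasing `stat`;
#'   attribute `descriptor`.
#' @export
ranked_list <- function(normalized, cells_a, cells_b, descriptor = "",
                        min_cells_detect = 1L, sigma_min = 1e-3) {
  cells_a <- resolve_cells(cells_a, colnames(normalized))
  cells_b <- resolve_cells(cells_b, colnames(normalized))
  if (!length(cells_a) || !length(cells_b))
    isr_stop("both cell sets must be nonempty", "isrmap_input_error")
  r <- bimod_lrt_all(normalized, cells_a, cells_b, sigma_min = sigma_min)
  n1 <- r$det_A * length(cells_a) + r$det_B * length(cells_b)
  keep <- n1 >= min_cells_detect
  direction <- sign(r$mean_A - r$mean_B)[keep]
  stat <- direction * (-r$log_p[keep] / log(10))
  out <- data.frame(gene = r$gene[keep], stat = stat,
                    lrt_stat = r$stat[keep], p_value = r$p[keep],
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(-out$stat, -out$lrt_stat, out$gene), ]
  rownames(out) <- NULL
  structure(out, descriptor = descriptor,
            class = c("ranked_list", "data.frame"))
}

resolve_cells <- function(cells, barcodes) {
  if (is.character(cells)) {
    idx <- match(cells, barcodes)
    if (anyNA(idx)) isr_stop("unknown barcode in cell set", "isrmap_input_error")
    idx
  } else as.integer(cells)
}
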