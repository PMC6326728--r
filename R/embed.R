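#' Depth-normalize and log-transform a count matrix
#'
#' Per barcode, counts are divided by the barcode total, multiplied by
#' `scale_factor` and transformed with `log1p` (natural log). Zeros stay
#' zero, so the result remains sparse. The normalized vector of a barcode is
#' invariant to rescaling its counts (sequencing depth).
#'
#' @param counts genes x barcodes sparse count matrix with no all-zero
#'   barcode (guaranteed after QC).
#' @param scale_factor depth scale (default 1e4).
#' @return sparse genes x barcodes matrix of normalized log expression.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) isr_stop("zero-total barcode; run QC first",
                                 "isrmap_input_error")
  x <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  x@x <- log1p(x@x / rep.int(totals, diff(x@p)) * scale_factor)
  x
}

#' Select variable genes by binned dispersion z-score
#'
#' For each gene the mean and dispersion (variance/mean) of normalized
#' expression are computed; genes are binned by mean into `n_bins`
#' equal-occupancy bins; dispersions are z-scored within each bin; genes
#' with z-score at or above `z_cutoff` and mean within `mean_bounds` are
#' returned in input order.
#'
#' @param normalized genes x barcodes normalized matrix
#'   (see [normalize_counts()]).
#' @param n_bins number of equal-occupancy mean bins (default 20).
#' @param z_cutoff dispersion z-score cutoff (default 1).
#' @param mean_bounds length-2 numeric, inclusive bounds on the gene mean on
#'   the normalized log scale (default `c(0.0125, 3)`).
#' @return character vector of selected gene ids, in input order.
#' @export
select_variable_genes <- function(normalized, n_bins = 20L, z_cutoff = 1,
                                  mean_bounds = c(0.0125, 3)) {
  mu <- Matrix::rowMeans(normalized)
  nz <- sum(mu > 0)
  if (nz < n_bins) isr_stop("fewer expressed genes than bins", "isrmap_input_error")
  ex2 <- Matrix::rowMeans(normalized^2)
  v <- (ex2 - mu^2) * ncol(normalized) / max(1, ncol(normalized) - 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)

  ok <- which(is.finite(disp))
  # equal-occupancy bins on the mean
  br <- unique(quantile(mu[ok], probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu[ok], breaks = br, include.lowest = TRUE)
  z <- rep(NA_real_, length(mu))
  for (b in levels(bins)) {
    idx <- ok[bins == b]
    m <- mean(disp[idx]); s <- sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  sel <- which(!is.na(z) & z >= z_cutoff &
                 mu >= mean_bounds[1] & mu <= mean_bounds[2])
  if (!length(sel)) {
    isr_stop("no variable genes pass; relax z_cutoff or mean_bounds",
             "isrmap_input_error")
  }
  rownames(normalized)[sel]
}

#' Principal-component embedding of cells
#'
#' Restricts the normalized matrix to `variable_genes`, centers and
#' unit-scales each gene (zero-variance genes are dropped with a warning),
#' and computes an exact PCA of cells, keeping the `n_pcs` components with
#' the largest variance. The decomposition is obtained from an
#' eigendecomposition of whichever Gram matrix (gene-gene or cell-cell) is
#' smaller, so it is deterministic at any size.
#'
#' @param normalized genes x barcodes normalized matrix.
#' @param variable_genes gene ids to use.
#' @param n_pcs number of components (default 50); truncated to the
#'   available rank bound `min(genes, cells) - 1`.
#' @return object of class `cell_embedding`: list with `barcode_ids`,
#'   `coordinates` (cells x PCs), `variance_explained` (fraction of total
#'   scaled variance per PC, nonincreasing), `variable_genes` (those used
#'   after dropping zero-variance genes).
#' @export
compute_pca <- function(normalized, variable_genes, n_pcs = 50L) {
  genes <- intersect(variable_genes, rownames(normalized))
  x <- t(as.matrix(normalized[genes, , drop = FALSE]))  # cells x genes
  sds <- apply(x, 2, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    isr_log("warn", sprintf("dropping %d zero-variance gene(s) before PCA", sum(drop)))
    x <- x[, !drop, drop = FALSE]
    genes <- genes[!drop]
  }
  if (ncol(x) < 2L) isr_stop("fewer than 2 usable variable genes", "isrmap_input_error")
  n <- nrow(x); d <- ncol(x)
  n_pcs <- min(n_pcs, d, n - 1L)
  x <- scale(x, center = TRUE, scale = TRUE)
  total_var <- d  # unit-scaled genes

  if (d <= n) {
    cv <- crossprod(x) / (n - 1)
    eg <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    rot <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    coords <- x %*% rot
  } else {
    gm <- tcrossprod(x) / (n - 1)
    eg <- eigen(gm, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    u <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    coords <- u %*% diag(sqrt(ev[seq_len(n_pcs)] * (n - 1)), n_pcs)
  }
  # deterministic sign: largest-|loading| coordinate of each PC nonnegative
  for (k in seq_len(n_pcs)) {
    j <- which.max(abs(coords[, k]))
    if (coords[j, k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("PC", seq_len(n_pcs))
  structure(list(barcode_ids = rownames(x),
                 coordinates = coords,
                 variance_explained = ev[seq_len(n_pcs)] / total_var,
                 variable_genes = genes),
            class = "cell_embedding")
}
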