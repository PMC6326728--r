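#' SVD eigengene decomposition of a bulk expression matrix
#'
#' Optionally transforms the genes x samples matrix with `ln(x + 1)`,
#' optionally centers each gene, and computes an exact singular value
#' decomposition `X = U S V'`. The right singular vectors ("eigengenes")
#' capture canonical expression patterns across samples; the columns of `U`
#' are the per-gene loadings on each eigengene. Components are ordered by
#' singular value, and a deterministic sign convention is applied: within
#' each component, the sample-vector entry of largest magnitude is made
#' nonnegative.
#'
#' @param expr genes x samples numeric matrix (e.g. TPM), finite, with
#'   dimnames; nonnegative if `log_transform`.
#' @param log_transform apply `log1p` first (default TRUE).
#' @param center center each gene (default TRUE; without centering the
#'   first component tracks mean expression rather than sample contrasts).
#' @return object of class `eigengene_decomposition`: list with `gene_ids`,
#'   `sample_ids`, `loadings` (genes x components, `U`), `singular_values`,
#'   `eigengenes` (samples x components, `V`), `variance_fraction`,
#'   `log_transform`, `center`.
#' @export
svd_decompose <- function(expr, log_transform = TRUE, center = TRUE) {
  x <- as.matrix(expr)
  if (nrow(x) < 2L || ncol(x) < 2L)
    isr_stop("need >= 2 genes and >= 2 samples", "isrmap_input_error")
  if (any(!is.finite(x))) isr_stop("non-finite entries in expression matrix",
                                   "isrmap_input_error")
  if (log_transform) {
    if (any(x < 0)) isr_stop("negative values under log transform",
                             "isrmap_input_error")
    x <- log1p(x)
  }
  if (center) x <- x - rowMeans(x)
  dec <- svd(x)
  for (k in seq_along(dec$d)) {
    j <- which.max(abs(dec$v[, k]))
    if (dec$v[j, k] < 0) {
      dec$v[, k] <- -dec$v[, k]
      dec$u[, k] <- -dec$u[, k]
    }
  }
  d2 <- dec$d^2
  structure(list(gene_ids = rownames(x), sample_ids = colnames(x),
                 loadings = dec$u, singular_values = dec$d,
                 eigengenes = dec$v,
                 variance_fraction = if (sum(d2) > 0) d2 / sum(d2) else d2,
                 log_transform = log_transform, center = center),
            class = "eigengene_decomposition")
}

#' Gene classes from an eigengene's loadings
#'
#' Applies the loading threshold: two-fold the mean of all absolute
#' loadings on the chosen component. Genes with loading above `+threshold`
#' form the up class, genes below `-threshold` the down class.
#'
#' @param decomposition an [svd_decompose()] result.
#' @param component component index (default 1).
#' @return object of class `gene_class_result`: list with `component`,
#'   `threshold`, `up_genes`, `down_genes`.
#' @export
gene_classes <- function(decomposition, component = 1L) {
  if (component < 1L || component > length(decomposition$singular_values))
    isr_stop("component out of range", "isrmap_input_error")
  loading <- decomposition$loadings[, component]
  threshold <- 2 * mean(abs(loading))
  structure(list(component = as.integer(component), threshold = threshold,
                 up_genes = decomposition$gene_ids[loading > threshold],
                 down_genes = decomposition$gene_ids[loading < -threshold]),
            class = "gene_class_result")
}

#' Variance fractions of an eigengene decomposition (scree values)
#' @param decomposition an [svd_decompose()] result.
#' @return numeric vector `s_k^2 / sum s^2`, nonincreasing, summing to 1.
#' @export
scree <- function(decomposition) {
  decomposition$variance_fraction
}

#' Sample projections onto eigengenes
#'
#' Coordinates are `singular value x eigengene entry` per sample, i.e. the
#' sample scores of the decomposition.
#'
#' @param decomposition an [svd_decompose()] result.
#' @param components component indices (default `c(1, 2)`).
#' @return samples x components numeric matrix with sample ids as rownames.
#' @export
project_samples <- function(decomposition, components = c(1L, 2L)) {
  if (any(components < 1L) ||
      any(components > length(decomposition$singular_values)))
    isr_stop("component out of range", "isrmap_input_error")
  coords <- sweep(decomposition$eigengenes[, components, drop = FALSE], 2,
                  decomposition$singular_values[components], "*")
  dimnames(coords) <- list(decomposition$sample_ids,
                           paste0("EG", components))
  coords
}
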