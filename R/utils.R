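#' @useDynLib isrmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as is
#' @importFrom stats rmultinom rnorm rlnorm runif qlnorm sd var quantile
#'   setNames pchisq p.adjust prcomp dist optimize
#' @importFrom utils head tail write.table read.table
NULL

# Logging: levels debug < info < warn. Controlled by option "isrmap.log_level"
# (default "info"). Every pipeline stage logs the parameter values it used.
.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

isr_log <- function(level = "info", ...) {
  thr <- getOption("isrmap.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[thr]]) {
    message(sprintf("[isrmap:%s] %s", level, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

isr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "isrmap_error")))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Validate a genes-by-barcodes UMI count matrix
#'
#' A count matrix in this package is a sparse `Matrix::dgCMatrix` (or any
#' matrix coercible to one) with genes as rows and droplet barcodes as
#' columns, unique non-empty dimnames on both axes, and nonnegative integer
#' entries (UMI units).
#'
#' @param counts matrix-like object to validate.
#' @return the validated matrix as a `dgCMatrix`, invisibly usable.
#' @export
validate_count_matrix <- function(counts) {
  if (is(counts, "nMatrix")) counts <- as(counts, "dMatrix")  # pattern MTX
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  gene_ids <- rownames(counts)
  barcode_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(barcode_ids)) {
    isr_stop("count matrix must carry gene (row) and barcode (column) ids",
             "isrmap_format_error")
  }
  if (anyDuplicated(gene_ids)) {
    isr_stop("duplicate gene ids in count matrix", "isrmap_format_error")
  }
  if (anyDuplicated(barcode_ids)) {
    isr_stop("duplicate barcode ids in count matrix", "isrmap_format_error")
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    isr_stop("count matrix entries must be nonnegative integers (UMIs)",
             "isrmap_format_error")
  }
  counts
}

# Deterministic formatting used for all numeric table output: 6 significant
# digits, so repeated runs are byte-comparable.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
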