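#' Read a 10x-style sparse count triple (MTX + barcodes + features)
#'
#' Reads a MatrixMarket coordinate matrix together with one-id-per-line
#' barcode and feature files (optionally gzipped) and returns a
#' genes-by-barcodes sparse count matrix. Both on-disk orientations
#' (genes x barcodes and barcodes x genes) occur in the wild; the
#' orientation is resolved by matching the MTX dimensions against the two
#' id-file lengths, and the result always has features as rows.
#'
#' @param matrix_path path to the MatrixMarket `.mtx` file.
#' @param barcodes_path path to the barcode id file (one per line).
#' @param features_path path to the feature/gene id file (one per line).
#' @return a `dgCMatrix` with gene ids as rownames and barcode ids as
#'   colnames; entries are UMI counts.
#' @examples
#' cm <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(2, 5),
#'                            dims = c(3, 2),
#'                            dimnames = list(paste0("g", 1:3), c("b1", "b2")))
#' d <- tempfile(); paths <- write_counts_10x(cm, d)
#' cm2 <- read_counts_10x(paths$matrix, paths$barcodes, paths$features)
#' all.equal(cm, cm2)
#' @export
read_counts_10x <- function(matrix_path, barcodes_path, features_path) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- read_id_file(barcodes_path)
  features <- read_id_file(features_path)
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    # features x barcodes on disk
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    m <- Matrix::t(m)
  } else {
    isr_stop(sprintf(
      "MTX dimensions %d x %d match neither %d features x %d barcodes nor its transpose",
      nrow(m), ncol(m), length(features), length(barcodes)),
      "isrmap_format_error")
  }
  if (anyDuplicated(features)) {
    isr_stop("duplicate ids in features file", "isrmap_format_error")
  }
  if (anyDuplicated(barcodes)) {
    isr_stop("duplicate ids in barcodes file", "isrmap_format_error")
  }
  dimnames(m) <- list(features, barcodes)
  validate_count_matrix(m)
}

read_id_file <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  # 10x features.tsv may carry extra columns (id, symbol, type); keep column 1
  vapply(strsplit(ids, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count matrix as a 10x-style triple
#'
#' Emits `matrix.mtx`, `barcodes.tsv` and `features.tsv` under `out_dir`,
#' readable back with [read_counts_10x()].
#'
#' @param counts genes x barcodes sparse count matrix with dimnames.
#' @param out_dir output directory, created if absent.
#' @return named list of the three file paths, invisibly.
#' @export
write_counts_10x <- function(counts, out_dir) {
  counts <- validate_count_matrix(counts)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    isr_stop(sprintf("cannot create output directory '%s'", out_dir),
             "isrmap_io_error")
  }
  paths <- list(matrix = file.path(out_dir, "matrix.mtx"),
                barcodes = file.path(out_dir, "barcodes.tsv"),
                features = file.path(out_dir, "features.tsv"))
  Matrix::writeMM(counts, paths$matrix)
  writeLines(colnames(counts), paths$barcodes)
  writeLines(rownames(counts), paths$features)
  invisible(paths)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are dropped with a logged warning.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of gene ids, with a
#'   `description` attribute (named character vector per set).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      isr_stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                       k, length(fields)), "isrmap_format_error")
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      isr_log("warn", sprintf("GMT set '%s': %d duplicate gene id(s) dropped",
                              fields[[1]], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    sets[[fields[[1]]]] <- genes
    desc[[fields[[1]]]] <- fields[[2]]
  }
  structure(sets, description = desc)
}

#' Write a gene-set collection to a GMT file
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gene_sets_gmt()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell-type marker reference table
#'
#' Two-column TSV with header `cell_type<TAB>gene`, one marker per row.
#'
#' @param path path to the TSV.
#' @return named list mapping cell-type name to character vector of marker
#'   gene ids.
#' @export
read_marker_reference <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(df))) {
    isr_stop("marker reference needs columns 'cell_type' and 'gene'",
             "isrmap_format_error")
  }
  ref <- split(df$gene, df$cell_type)
  validate_marker_reference(ref)
}

#' @rdname read_marker_reference
#' @param ref named list mapping cell type to marker gene ids.
#' @export
write_marker_reference <- function(ref, path) {
  df <- data.frame(cell_type = rep(names(ref), lengths(ref)),
                   gene = unlist(ref, use.names = FALSE))
  write_tsv(df, path)
}

validate_marker_reference <- function(ref) {
  if (!length(ref) || is.null(names(ref)) || anyDuplicated(names(ref))) {
    isr_stop("marker reference must map unique cell-type names to markers",
             "isrmap_format_error")
  }
  if (any(lengths(ref) == 0L)) {
    isr_stop("every cell type needs >= 1 marker gene", "isrmap_format_error")
  }
  lapply(ref, unique)
}
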