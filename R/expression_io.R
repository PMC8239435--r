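#' Construct an expression matrix container
#'
#' Light container for a cells x genes expression matrix with unique gene
#' and cell identifiers and a layer tag recording whether the values are raw
#' UMI counts or normalized log-expression.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param gene_ids Character vector of unique gene symbols (columns).
#' @param cell_ids Character vector of unique cell barcodes (rows).
#' @param layer_tag `"counts"` or `"normalized"`. If `NULL`, inferred:
#'   `"counts"` when all entries are non-negative integers.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              cell_ids = rownames(values),
                              layer_tag = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("non-numeric entries", call. = FALSE)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required", call. = FALSE)
  gene_ids <- trimws(as.character(gene_ids))
  cell_ids <- trimws(as.character(cell_ids))
  if (length(gene_ids) != ncol(values) || length(cell_ids) != nrow(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  if (is.null(layer_tag)) {
    layer_tag <- if (all(values == floor(values))) "counts" else "normalized"
  }
  layer_tag <- match.arg(layer_tag, c("counts", "normalized"))
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 layer_tag = layer_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes [%s]\n",
              length(x$cell_ids), length(x$gene_ids), x$layer_tag))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a single-cell expression matrix
#'
#' Reads Matrix-Market sparse triplets (CellRanger-style: `matrix.mtx` with
#' adjacent `genes.tsv`/`features.tsv` and `barcodes.tsv`, genes as rows)
#' or dense CSV/TSV matrices (first column = row identifiers). The result
#' is always oriented cells x genes.
#'
#' @param path Path to the matrix file (`.mtx`, `.csv` or `.tsv`).
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`; default guessed from the
#'   file extension.
#' @param orientation On-disk orientation of a dense matrix, or an override
#'   for the MTX convention: `"genes_x_cells"` (MTX default) or
#'   `"cells_x_genes"`.
#' @return An [expression_matrix()] with `layer_tag` inferred from the
#'   values (`counts` if all integer).
#' @export
read_expression <- function(path,
                            format = c("auto", "mtx", "csv", "tsv"),
                            orientation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "mtx") {
    if (is.null(orientation)) orientation <- "genes_x_cells"
    dir <- dirname(path)
    gene_file <- sidecar_file(dir, c("genes.tsv", "features.tsv", "genes.txt"))
    bc_file <- sidecar_file(dir, c("barcodes.tsv", "barcodes.txt"))
    if (is.null(gene_file) || is.null(bc_file))
      stop("missing sidecar gene/barcode files next to ", path, call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    genes <- utils::read.delim(gene_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bc_file, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (orientation == "genes_x_cells") m <- t(m)
    return(expression_matrix(m, gene_ids = genes, cell_ids = cells))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  if (is.null(orientation)) orientation <- "cells_x_genes"
  orientation <- match.arg(orientation, c("cells_x_genes", "genes_x_cells"))
  if (orientation == "genes_x_cells") m <- t(m)
  expression_matrix(m, gene_ids = colnames(m), cell_ids = rownames(m))
}

sidecar_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]: writes either a dense CSV/TSV
#' (cells x genes, row names = barcodes) or a Matrix-Market triplet
#' (genes as rows, with `genes.tsv` and `barcodes.tsv` sidecars).
#'
#' @param mat An [expression_matrix()].
#' @param path Output file path (for `mtx`, the matrix file; sidecars are
#'   written next to it).
#' @param format `"mtx"`, `"csv"` or `"tsv"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path,
                             format = c("auto", "mtx", "csv", "tsv")) {
  stopifnot(inherits(mat, "expression_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(mat$values), sparse = TRUE), path)
    utils::write.table(mat$gene_ids,
                       file.path(dirname(path), "genes.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(mat$cell_ids,
                       file.path(dirname(path), "barcodes.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = mat$cell_ids, mat$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Median-library-size normalization
#'
#' Scales each cell's counts to the median library size across cells and
#' applies a `log(1 + x)` transform. This is a simple stand-in for pooled
#' deconvolution normalization; pre-normalized matrices from other tools
#' are accepted anywhere a normalized layer is required.
#'
#' @param mat An [expression_matrix()] with `layer_tag = "counts"`.
#' @return An [expression_matrix()] with `layer_tag = "normalized"`.
#' @export
normalize_counts <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (mat$layer_tag != "counts")
    stop("normalize_counts expects a counts layer", call. = FALSE)
  totals <- rowSums(mat$values)
  if (any(totals == 0))
    stop("cell(s) with zero total count: ",
         paste(mat$cell_ids[totals == 0], collapse = ", "), call. = FALSE)
  target <- stats::median(totals)
  scaled <- mat$values * (target / totals)
  expression_matrix(log1p(scaled), gene_ids = mat$gene_ids,
                    cell_ids = mat$cell_ids, layer_tag = "normalized")
}

#' Read a gene signature from a plain-text list
#'
#' One gene symbol per line; lines starting with `#` are comments.
#' Order is preserved; duplicates are removed with a warning.
#'
#' @param path Path to the gene list.
#' @param name Signature name; defaults to the file name without extension.
#' @return A `gene_signature` object (list with `name`, `genes`).
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    stop("no gene symbols in ", path, " after comment stripping",
         call. = FALSE)
  if (anyDuplicated(lines)) {
    warning("duplicate symbols removed from ", basename(path), ": ",
            paste(unique(lines[duplicated(lines)]), collapse = ", "),
            call. = FALSE)
    lines <- unique(lines)
  }
  gene_signature(lines, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct a gene signature
#'
#' @param genes Character vector of unique gene symbols, order preserved.
#' @param name Signature name.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(genes, name = "signature") {
  genes <- trimws(as.character(genes))
  if (!length(genes)) stop("empty gene signature", call. = FALSE)
  if (anyDuplicated(genes)) {
    warning("duplicate symbols removed from signature '", name, "'",
            call. = FALSE)
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes (%s%s)\n", x$name,
              length(x$genes),
              paste(utils::head(x$genes, 5), collapse = ", "),
              if (length(x$genes) > 5) ", ..." else ""))
  invisible(x)
}

#' Read a cell-metadata table
#'
#' TSV with at least columns `cell_id` and `condition`; an optional
#' `cluster` column is kept if present.
#'
#' @param path Path to the TSV file.
#' @return A data frame with one row per cell.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "condition") %in% names(df)))
    stop("metadata must have columns 'cell_id' and 'condition'",
         call. = FALSE)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in metadata", call. = FALSE)
  df
}

## every matrix cell must have a metadata row
check_metadata <- function(mat, metadata) {
  missing <- setdiff(mat$cell_ids, metadata$cell_id)
  if (length(missing))
    stop("cells missing from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "", call. = FALSE)
  metadata[match(mat$cell_ids, metadata$cell_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
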