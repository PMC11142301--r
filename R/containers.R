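#' Labeled single-cell expression dataset
#'
#' Bundle a sparse cell-by-gene count matrix with per-cell metadata (group,
#' optional cell type) and per-gene flags (mitochondrial). This is the common
#' currency of all pipeline stages; cells are rows, genes are columns.
#'
#' @param counts sparse or dense cell x gene count matrix with row (barcode)
#'   and column (gene) names. Coerced to `CsparseMatrix`.
#' @param cells data.frame with one row per cell; must contain a `barcode`
#'   column matching `rownames(counts)` and a `group` column. An optional
#'   `cell_type` column is carried along.
#' @param genes data.frame with one row per gene; must contain `gene`
#'   matching `colnames(counts)` and a logical `mito` flag. If `NULL`, the
#'   flag is derived from the conventional "MT-" gene-name prefix.
#' @return An object of class `sc_dataset`: a list with elements `counts`,
#'   `cells`, `genes`.
#' @export
sc_dataset <- function(counts, cells, genes = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) && nrow(counts) > 0 ||
      is.null(colnames(counts)) && ncol(counts) > 0)
    stop("counts must have cell (row) and gene (column) names")
  if (!all(c("barcode", "group") %in% names(cells)))
    stop("cells metadata needs 'barcode' and 'group' columns")
  if (nrow(counts) > 0 &&
      !identical(as.character(cells$barcode), rownames(counts)))
    stop("cells$barcode must match rownames(counts) in order")
  if (is.null(genes))
    genes <- data.frame(gene = colnames(counts),
                        mito = startsWith(colnames(counts), "MT-"))
  if (ncol(counts) > 0 &&
      !identical(as.character(genes$gene), colnames(counts)))
    stop("genes$gene must match colnames(counts) in order")
  if (!is.logical(genes$mito)) stop("genes$mito must be logical")
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "sc_dataset")
}

#' @exportS3Method base::print
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  groups:", paste(names(table(x$cells$group)), "=",
                         as.vector(table(x$cells$group)), collapse = ", "),
      "\n")
  if ("cell_type" %in% names(x$cells))
    cat("  cell types:", length(unique(x$cells$cell_type)), "\n")
  cat("  mitochondrial genes:", sum(x$genes$mito), "\n")
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

#' Subset a dataset by cells and/or genes
#'
#' @param data an `sc_dataset`
#' @param cells,genes indices, logical masks, or barcode / gene names;
#'   `NULL` keeps everything.
#' @return the subset `sc_dataset`
#' @export
subset_dataset <- function(data, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_len(nrow(data$counts)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(data$counts)) else genes
  if (is.character(ci)) ci <- match(ci, rownames(data$counts))
  if (is.character(gi)) gi <- match(gi, colnames(data$counts))
  sc_dataset(data$counts[ci, gi, drop = FALSE],
             data$cells[ci, , drop = FALSE],
             data$genes[gi, , drop = FALSE])
}

#' Concatenate datasets sharing a gene universe
#'
#' @param ... `sc_dataset` objects with identical gene tables
#' @return a single `sc_dataset` with cells stacked in input order
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  g1 <- parts[[1]]$genes
  for (p in parts[-1])
    if (!identical(p$genes$gene, g1$gene))
      stop("datasets do not share a gene universe")
  counts <- do.call(rbind, lapply(parts, `[[`, "counts"))
  cols <- Reduce(intersect, lapply(parts, function(p) names(p$cells)))
  cells <- do.call(rbind, lapply(parts, function(p) p$cells[, cols, drop = FALSE]))
  rownames(cells) <- NULL
  sc_dataset(counts, cells, g1)
}

#' Write a dataset as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, the conventional on-disk orientation),
#' `genes.tsv` (gene, mito) and `cells.tsv` (barcode, group, cell_type).
#'
#' @param data an `sc_dataset`
#' @param path directory to create/write into
#' @return `path`, invisibly
#' @export
write_dataset <- function(data, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(data$counts), file.path(path, "matrix.mtx"))
  utils::write.table(data$genes, file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- data$cells
  if (!"cell_type" %in% names(cells)) cells$cell_type <- NA
  utils::write.table(cells, file.path(path, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`
#' @return an `sc_dataset`
#' @export
read_dataset <- function(path) {
  m <- Matrix::t(Matrix::readMM(file.path(path, "matrix.mtx")))
  genes <- utils::read.delim(file.path(path, "genes.tsv"),
                             colClasses = c("character", "logical"))
  cells <- utils::read.delim(file.path(path, "cells.tsv"),
                             colClasses = "character")
  if (all(is.na(cells$cell_type))) cells$cell_type <- NULL
  dimnames(m) <- list(cells$barcode, genes$gene)
  sc_dataset(m, cells, genes)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path
#' @return named list of character vectors of gene identifiers
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
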