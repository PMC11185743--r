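#' Construct a gene-by-cell count matrix container
#'
#' The universal substrate of the pipeline: a sparse non-negative integer
#' matrix of molecule counts (genes in rows, cells in columns) together with
#' per-cell and per-gene annotation tables.
#'
#' @param counts matrix or \code{\link[Matrix]{dgCMatrix}} of non-negative
#'   counts with unique rownames (gene ids) and colnames (cell ids).
#' @param cell_meta data.frame keyed by cell id (rownames).  Recognised
#'   columns include \code{sample}, \code{genotype}, \code{x_um},
#'   \code{y_um}, \code{volume_um3} and truth columns written by the
#'   simulator.  Missing rows are filled with an empty frame.
#' @param gene_meta data.frame keyed by gene id (rownames).  Logical columns
#'   \code{is_mito} and \code{is_ribo} flag mitochondrial/ribosomal genes;
#'   both default to \code{FALSE}.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} (dgCMatrix), \code{cell_meta}, \code{gene_meta}.
#' @export
count_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  dn <- dimnames(counts)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(dimnames(counts)) && !is.null(dn)) dimnames(counts) <- dn
  if (is.null(rownames(counts))) rownames(counts) <- dn[[1]]
  if (is.null(colnames(counts))) colnames(counts) <- dn[[2]]
  # zero-extent dimensions legitimately carry NULL names
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      (is.null(colnames(counts)) && ncol(counts) > 0))
    stop("counts must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  v <- counts@x
  if (length(v) && (any(!is.finite(v)) || any(v < 0)))
    stop("counts must be finite and non-negative")
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = colnames(counts))
  if (is.null(gene_meta))
    gene_meta <- data.frame(row.names = rownames(counts))
  if (!all(colnames(counts) %in% rownames(cell_meta)))
    stop("cell_meta missing rows for some cells")
  if (!all(rownames(counts) %in% rownames(gene_meta)))
    stop("gene_meta missing rows for some genes")
  cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
  gene_meta <- gene_meta[rownames(counts), , drop = FALSE]
  if (is.null(gene_meta$is_mito)) gene_meta$is_mito <- FALSE
  if (is.null(gene_meta$is_ribo)) gene_meta$is_ribo <- FALSE
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' Subset a count_matrix by genes and/or cells
#' @param x count_matrix
#' @param i gene index/names
#' @param j cell index/names
#' @param ... ignored
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               x$cell_meta[colnames(x$counts[, j, drop = FALSE]), , drop = FALSE],
               x$gene_meta[rownames(x$counts[i, , drop = FALSE]), , drop = FALSE])
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  if (ncol(x$cell_meta))
    cat("cell_meta columns:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supports the MatrixMarket triplet convention used by single-cell
#' pipelines (\code{matrix.mtx} + \code{genes.tsv} + \code{barcodes.tsv},
#' with optional \code{cell_meta.csv} / \code{gene_meta.csv} sidecars) and a
#' dense CSV with genes in rows.
#'
#' @param path directory (mtx) or file (csv).
#' @param format "mtx" or "csv".
#' @return a \code{\link{count_matrix}}.
#' @export
read_count_matrix <- function(path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop(sprintf("matrix is %d x %d but sidecars carry %d genes / %d cells",
                   nrow(m), ncol(m), length(genes), length(cells)))
    dimnames(m) <- list(genes, cells)
    cm <- gm <- NULL
    cpath <- file.path(path, "cell_meta.csv")
    gpath <- file.path(path, "gene_meta.csv")
    if (file.exists(cpath))
      cm <- utils::read.csv(cpath, row.names = 1, check.names = FALSE)
    if (file.exists(gpath))
      gm <- utils::read.csv(gpath, row.names = 1, check.names = FALSE)
    count_matrix(m, cm, gm)
  } else {
    m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    count_matrix(m)
  }
}

#' Write a count matrix to disk (MatrixMarket triplet + sidecars)
#'
#' @param x count_matrix
#' @param path output directory, created if absent.
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(path, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(path, "barcodes.tsv"))
  if (ncol(x$cell_meta))
    utils::write.csv(x$cell_meta, file.path(path, "cell_meta.csv"))
  if (ncol(x$gene_meta))
    utils::write.csv(x$gene_meta, file.path(path, "gene_meta.csv"))
  invisible(path)
}
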