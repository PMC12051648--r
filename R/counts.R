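#' Construct a sparse gene-by-cell count matrix with size factors
#'
#' @param counts Sparse (or dense) nonnegative integer matrix, genes in rows,
#'   cells in columns; `dimnames` give gene and cell ids.
#' @param size_factors Optional positive per-cell normalization constants
#'   (the offsets pi_j of the expression model). Defaults to per-cell total
#'   counts divided by their mean.
#' @return A `cosicc_counts` object (list with `counts`, `genes`, `cells`,
#'   `size_factors`).
#' @export
count_matrix <- function(counts, size_factors = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_cosicc("counts must carry gene rownames and cell colnames", "schema")
  v <- counts@x
  if (any(v < 0) || any(v != round(v)))
    stop_cosicc("counts must be nonnegative integers", "format")
  tot <- Matrix::colSums(counts)
  if (is.null(size_factors)) {
    if (any(tot == 0))
      stop_cosicc(paste0("cell(s) with zero total count: ",
                         paste(head(colnames(counts)[tot == 0], 5),
                               collapse = ", ")), "zero_count_cell")
    size_factors <- tot / mean(tot)
  } else {
    size_factors <- as.numeric(size_factors)
    if (length(size_factors) != ncol(counts))
      stop_cosicc("size_factors length must equal the number of cells",
                  "schema")
    if (any(!is.finite(size_factors)) || any(size_factors <= 0))
      stop_cosicc("size_factors must be positive and finite", "validation")
  }
  names(size_factors) <- colnames(counts)
  structure(list(counts = counts,
                 genes = rownames(counts),
                 cells = colnames(counts),
                 size_factors = size_factors),
            class = "cosicc_counts")
}

#' Read counts from MatrixMarket + sidecar files
#'
#' @param mtx_path MatrixMarket coordinate file (genes x cells, integer).
#' @param genes_path One-column, headerless gene-id file (one per matrix row).
#' @param cells_path One-column, headerless cell-id file (one per column).
#' @return A [count_matrix()] with size factors initialized to library size
#'   over mean library size.
#' @export
load_counts <- function(mtx_path, genes_path, cells_path) {
  for (p in c(mtx_path, genes_path, cells_path))
    if (!file.exists(p)) stop_cosicc(paste0("file not found: ", p), "io")
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  cells <- readLines(cells_path)
  cells <- cells[nzchar(cells)]
  if (length(genes) != nrow(m))
    stop_cosicc(sprintf(
      "gene sidecar has %d entries but matrix declares %d rows",
      length(genes), nrow(m)), "dimension_mismatch")
  if (length(cells) != ncol(m))
    stop_cosicc(sprintf(
      "cell sidecar has %d entries but matrix declares %d columns",
      length(cells), ncol(m)), "dimension_mismatch")
  dimnames(m) <- list(genes, cells)
  count_matrix(m)
}

#' Write counts as MatrixMarket + sidecars
#'
#' @param cm A [count_matrix()].
#' @param mtx_path,genes_path,cells_path Output paths.
#' @param size_factors_path Optional TSV (cell_id, size_factor) output.
#' @return `mtx_path`, invisibly.
#' @export
write_counts <- function(cm, mtx_path, genes_path, cells_path,
                         size_factors_path = NULL) {
  Matrix::writeMM(cm$counts, mtx_path)
  writeLines(cm$genes, genes_path)
  writeLines(cm$cells, cells_path)
  if (!is.null(size_factors_path))
    write.table(data.frame(cell_id = cm$cells,
                           size_factor = unname(cm$size_factors)),
                size_factors_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(mtx_path)
}

#' Subset a count matrix by genes and/or cells
#'
#' @param cm A [count_matrix()].
#' @param genes,cells Character vectors (order respected); `NULL` keeps all.
#' @return A [count_matrix()].
#' @export
subset_counts <- function(cm, genes = NULL, cells = NULL) {
  genes <- genes %||% cm$genes
  cells <- cells %||% cm$cells
  missg <- setdiff(genes, cm$genes)
  missc <- setdiff(cells, cm$cells)
  if (length(missg) > 0)
    stop_cosicc(paste0("unknown gene id(s): ",
                       paste(head(missg, 5), collapse = ", ")), "validation")
  if (length(missc) > 0)
    stop_cosicc(paste0("unknown cell id(s): ",
                       paste(head(missc, 5), collapse = ", ")), "validation")
  structure(list(counts = cm$counts[genes, cells, drop = FALSE],
                 genes = genes, cells = cells,
                 size_factors = cm$size_factors[cells]),
            class = "cosicc_counts")
}

#' Log-normalized expression
#'
#' `log1p(count / size_factor)`, the standard log-normalization used for
#' signature scoring, temporal-gene selection and pseudotime.
#'
#' @param cm A [count_matrix()].
#' @param dense Return a base dense matrix (default) or keep sparse.
#' @return Genes x cells matrix of log-normalized expression.
#' @export
logcounts <- function(cm, dense = TRUE) {
  x <- cm$counts
  x@x <- x@x / rep.int(cm$size_factors, diff(x@p))
  x <- log1p(x)
  if (dense) as.matrix(x) else x
}

#' Check that counts and cell table describe the same cells
#'
#' @param cm A [count_matrix()].
#' @param table A [cell_table()].
#' @return List with `shared`, `only_counts`, `only_table` cell-id vectors.
#' @export
match_cells <- function(cm, table) {
  shared <- intersect(cm$cells, table$cell_id)
  list(shared = shared,
       only_counts = setdiff(cm$cells, table$cell_id),
       only_table = setdiff(table$cell_id, cm$cells))
}

#' @export
print.cosicc_counts <- function(x, ...) {
  cat("<cosicc_counts> ", length(x$genes), " genes x ", length(x$cells),
      " cells; ", length(x$counts@x), " nonzero entries\n", sep = "")
  invisible(x)
}
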