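#' Construct an expression matrix object
#'
#' Container for a nonnegative gene x cell expression matrix with unique gene
#' and cell identifiers. The `unit` field records whether values are raw
#' counts or counts per million (CPM).
#'
#' @param values numeric matrix (base or [Matrix::Matrix]), genes in rows,
#'   cells in columns, all values nonnegative and non-missing.
#' @param genes character vector of unique gene identifiers (row names).
#' @param cells character vector of unique cell identifiers (column names).
#' @param unit `"counts"` or `"cpm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, cells, unit = c("counts", "cpm")) {
  unit <- match.arg(unit)
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (nrow(values) != length(genes) || ncol(values) != length(cells))
    stop("matrix dimensions (", nrow(values), " x ", ncol(values),
         ") do not match ", length(genes), " genes x ", length(cells), " cells")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(genes[duplicated(genes)]), 5), collapse = ", "))
  if (anyDuplicated(cells))
    stop("duplicate cell identifiers: ",
         paste(utils::head(unique(cells[duplicated(cells)]), 5), collapse = ", "))
  vals <- if (inherits(values, "sparseMatrix")) values@x else as.numeric(values)
  if (anyNA(vals)) stop("expression matrix contains missing values")
  if (any(vals < 0)) stop("expression matrix contains negative values")
  dimnames(values) <- list(genes, cells)
  structure(list(values = values, genes = genes, cells = cells, unit = unit),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", length(x$genes), " genes x ", length(x$cells),
      " cells (unit: ", x$unit, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Load an expression matrix from disk
#'
#' Reads either a MatrixMarket (MTX) coordinate file with one-column gene and
#' cell sidecar files, or a dense TSV with gene rows, a header row of cell
#' identifiers and the gene identifier in the first column. Values must be
#' nonnegative; entries omitted from an MTX file are zeros.
#'
#' @param matrix_path path to the `.mtx` or dense `.tsv` file.
#' @param genes_path,cells_path sidecar paths (one identifier per line);
#'   required for MTX input, ignored for dense TSV.
#' @return An [expression_matrix()] with unit `"counts"`.
#' @export
load_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL) {
  if (!file.exists(matrix_path)) stop("expression file not found: ", matrix_path)
  is_mtx <- grepl("\\.mtx(\\.gz)?$", matrix_path) ||
    startsWith(readLines(matrix_path, n = 1L), "%%MatrixMarket")
  if (is_mtx) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input requires both a gene and a cell sidecar file")
    m <- tryCatch(Matrix::readMM(matrix_path),
                  error = function(e) stop("malformed MTX file '", matrix_path,
                                           "': ", conditionMessage(e)))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (length(genes) != nrow(m))
      stop("gene sidecar lists ", length(genes), " genes but matrix has ",
           nrow(m), " rows")
    if (length(cells) != ncol(m))
      stop("cell sidecar lists ", length(cells), " cells but matrix has ",
           ncol(m), " columns")
    expression_matrix(methods::as(m, "CsparseMatrix"), genes, cells, "counts")
  } else {
    tab <- tryCatch(
      utils::read.table(matrix_path, header = TRUE, sep = "\t",
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("malformed TSV file '", matrix_path, "': ",
                               conditionMessage(e)))
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression values in ", matrix_path)
    expression_matrix(vals, genes, colnames(tab)[-1L], "counts")
  }
}

#' Construct a cell annotation object
#'
#' @param cell_to_type named character vector mapping cell identifier to
#'   cell-type label.
#' @return An object of class `cell_annotation` with `types` in
#'   first-appearance order.
#' @export
cell_annotation <- function(cell_to_type) {
  if (anyDuplicated(names(cell_to_type)))
    stop("duplicate cell identifiers in annotation")
  types <- unique(unname(cell_to_type))
  if (length(types) < 2L)
    stop("at least 2 distinct cell types are required, got ", length(types))
  structure(list(cell_to_type = cell_to_type, types = types),
            class = "cell_annotation")
}

#' @export
print.cell_annotation <- function(x, ...) {
  cat("cell_annotation: ", length(x$cell_to_type), " cells, ",
      length(x$types), " types (", paste(x$types, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Load cell-type annotations and align them with an expression matrix
#'
#' Reads a two-column TSV (`cell_id`, `cell_type`, with header). Cells present
#' in the expression matrix but missing from the annotation are dropped from
#' downstream analysis with a warning, as are annotated cells absent from the
#' matrix. Cell types appear in first-appearance order over the retained cells.
#'
#' @param path annotation TSV path.
#' @param expr an [expression_matrix()].
#' @return A `cell_annotation` restricted to cells shared with `expr`.
#' @export
load_annotation <- function(path, expr) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("annotation must have columns cell_id and cell_type")
  ann <- stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  if (anyDuplicated(names(ann))) stop("duplicate cell_id in annotation file")
  extra <- setdiff(names(ann), expr$cells)
  if (length(extra))
    warning(length(extra), " annotated cell(s) absent from the expression ",
            "matrix were ignored")
  unannotated <- setdiff(expr$cells, names(ann))
  if (length(unannotated))
    warning(length(unannotated), " cell(s) in the expression matrix have no ",
            "annotation and are dropped from the analysis")
  keep <- intersect(expr$cells, names(ann))
  if (!length(keep)) stop("no overlap between annotated cells and the matrix")
  ann <- ann[keep]
  out <- cell_annotation(ann)
  small <- table(ann)[table(ann) < 10L]
  if (length(small))
    warning("cell type(s) with fewer than 10 cells: ",
            paste(names(small), small, sep = "=", collapse = ", "))
  out
}

#' Counts-per-million normalization
#'
#' Scales every cell (column) to a library size of one million:
#' `cpm = counts * 1e6 / colsum`. Cells with zero library size are an error —
#' they should have been removed by upstream quality control.
#'
#' @param expr an [expression_matrix()] with unit `"counts"`.
#' @return The matrix with unit `"cpm"`; every column sums to 1e6.
#' @export
cpm_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$unit != "counts") stop("cpm_normalize expects unit 'counts'")
  libsize <- Matrix::colSums(expr$values)
  bad <- which(libsize <= 0)
  if (length(bad))
    stop("cell(s) with zero library size: ",
         paste(utils::head(expr$cells[bad], 5), collapse = ", "))
  vals <- expr$values %*% Matrix::Diagonal(x = 1e6 / libsize)
  if (!inherits(expr$values, "sparseMatrix")) vals <- as.matrix(vals)
  expression_matrix(vals, expr$genes, expr$cells, "cpm")
}

#' Per-cell-type mean expression
#'
#' Arithmetic mean of each gene over the cells of each annotated type,
#' computed on CPM values (cell type-specificity is defined on CPM).
#'
#' @param expr an [expression_matrix()] with unit `"cpm"`.
#' @param ann a `cell_annotation`; only cells present in both are used.
#' @return An object of class `mean_expression` with fields `genes`, `types`,
#'   `means` (genes x k matrix) and `n_cells` (named per-type cell counts).
#' @export
mean_by_cell_type <- function(expr, ann) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(ann, "cell_annotation"))
  if (expr$unit != "cpm")
    stop("mean_by_cell_type expects CPM values; run cpm_normalize() first")
  cells <- intersect(expr$cells, names(ann$cell_to_type))
  if (!length(cells)) stop("no annotated cells present in the matrix")
  type_of <- ann$cell_to_type[cells]
  types <- ann$types[ann$types %in% type_of]
  means <- matrix(NA_real_, length(expr$genes), length(types),
                  dimnames = list(expr$genes, types))
  n_cells <- integer(length(types))
  names(n_cells) <- types
  for (ty in types) {
    cols <- cells[type_of == ty]
    n_cells[ty] <- length(cols)
    means[, ty] <- Matrix::rowMeans(expr$values[, cols, drop = FALSE])
  }
  structure(list(genes = expr$genes, types = types, means = means,
                 n_cells = n_cells),
            class = "mean_expression")
}

#' @export
print.mean_expression <- function(x, ...) {
  cat("mean_expression: ", length(x$genes), " genes x ", length(x$types),
      " cell types; cells per type: ",
      paste(names(x$n_cells), x$n_cells, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
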