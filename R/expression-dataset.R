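#' Expression dataset container
#'
#' A light S3 container for a cell-by-gene expression matrix plus per-cell
#' metadata. The matrix is stored sparse (cells in rows, genes in columns);
#' the `layer` tag records whether values are raw counts or log-normalized.
#'
#' @param values Cell x gene matrix (coerced to `Matrix::dgCMatrix`), rows
#'   named by cell id and columns by gene id.
#' @param cells Tibble of per-cell metadata. Must contain `cell_id`; the
#'   pipeline additionally expects `patient`, `group`, `cell_type`,
#'   `n_genes_detected` and `pct_mito`.
#' @param layer Either `"counts"` or `"lognorm"`.
#'
#' @return An object of class `expr_dataset` with fields `values`, `cells`,
#'   `genes` and `layer`.
#' @export
expr_dataset <- function(values, cells, layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (!inherits(values, "Matrix")) {
    values <- Matrix::Matrix(as.matrix(values) * 1.0, sparse = TRUE)
  }
  values <- methods::as(methods::as(values, "generalMatrix"),
                        "CsparseMatrix")
  if (!methods::is(values, "dMatrix")) values <- values * 1.0
  cells <- tibble::as_tibble(cells)
  if (!"cell_id" %in% names(cells)) {
    stop("cell metadata must contain a 'cell_id' column", call. = FALSE)
  }
  if (nrow(cells) != nrow(values)) {
    stop("metadata rows (", nrow(cells), ") must match matrix rows (",
         nrow(values), ")", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("expression matrix must have gene column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("gene ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("cell ids must be unique", call. = FALSE)
  }
  rownames(values) <- cells$cell_id
  if ("pct_mito" %in% names(cells) &&
      any(cells$pct_mito < 0 | cells$pct_mito > 1, na.rm = TRUE)) {
    stop("pct_mito must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(values = values, cells = cells, genes = colnames(values),
         layer = layer),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", nrow(x$values), " cells x ", ncol(x$values),
      " genes [layer: ", x$layer, "]\n", sep = "")
  extra <- setdiff(names(x$cells), "cell_id")
  if (length(extra)) cat("cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Subset an expression dataset by cells and/or genes
#'
#' @param x An `expr_dataset`.
#' @param cells Cell ids, logical mask or integer indices (rows).
#' @param genes Gene ids, logical mask or integer indices (columns).
#' @return The subset `expr_dataset`, metadata kept in step.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "expr_dataset"))
  ci <- if (is.null(cells)) seq_len(nrow(x$values)) else cells
  if (is.character(ci)) ci <- match(ci, x$cells$cell_id)
  gi <- if (is.null(genes)) seq_len(ncol(x$values)) else genes
  if (is.character(gi)) gi <- match(gi, x$genes)
  if (anyNA(ci)) stop("unknown cell id in subset", call. = FALSE)
  if (anyNA(gi)) stop("unknown gene id in subset", call. = FALSE)
  expr_dataset(x$values[ci, gi, drop = FALSE], x$cells[ci, , drop = FALSE],
               layer = x$layer)
}

#' Per-cell metadata of an expression dataset as a tibble
#'
#' @param x An `expr_dataset`.
#' @return The cell metadata tibble.
#' @export
cell_info <- function(x) {
  stopifnot(inherits(x, "expr_dataset"))
  x$cells
}

# Dense matrix of the current layer; internal helper for rank-based scores.
dense_values <- function(x) {
  m <- as.matrix(x$values)
  dimnames(m) <- list(x$cells$cell_id, x$genes)
  m
}

#' Tidy an expression dataset into long form
#'
#' @param x An `expr_dataset`.
#' @param genes Optional gene ids to restrict to (long output is large).
#' @param ... Unused.
#' @return Tibble with `cell_id`, `gene`, `value` joined to cell metadata.
#' @export
tidy.expr_dataset <- function(x, genes = NULL, ...) {
  d <- if (is.null(genes)) x else subset_cells(x, genes = genes)
  m <- dense_values(d)
  tibble::tibble(
    cell_id = rep(rownames(m), times = ncol(m)),
    gene = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  ) |>
    dplyr::left_join(d$cells, by = "cell_id")
}

#' @export
glance.expr_dataset <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$values), n_genes = ncol(x$values), layer = x$layer,
    n_patients = if ("patient" %in% names(x$cells))
      dplyr::n_distinct(x$cells$patient) else NA_integer_,
    sparsity = 1 - Matrix::nnzero(x$values) / prod(dim(x$values))
  )
}
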