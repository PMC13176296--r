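#' Write an expression dataset as Matrix Market plus TSV metadata
#'
#' Writes `matrix.mtx` (cells in rows, genes in columns), `barcodes.tsv`
#' (cell ids), `features.tsv` (gene ids) and `cells.tsv` (the full cell
#' metadata table) into `dir`.
#'
#' @param data An [expr_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(data, dir) {
  stopifnot(inherits(data, "expr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(data$values, file.path(dir, "matrix.mtx"))
  writeLines(data$cells$cell_id, file.path(dir, "barcodes.tsv"))
  writeLines(data$genes, file.path(dir, "features.tsv"))
  utils::write.table(data$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression dataset
#'
#' Accepts either a directory holding the Matrix Market triplet
#' (`matrix.mtx` with cells in rows, `barcodes.tsv`, `features.tsv`, and
#' optionally `cells.tsv` metadata) or a dense TSV file whose first column is
#' `cell_id` and remaining columns are genes.
#'
#' @param path Directory (MTX layout) or dense TSV file.
#' @param metadata Optional path to a cell-metadata TSV (`cell_id` keyed);
#'   for the MTX layout, `cells.tsv` inside `path` is used by default.
#' @param layer `"counts"` or `"lognorm"` tag for the values read.
#' @return An [expr_dataset()].
#' @export
read_expression <- function(path, metadata = NULL,
                            layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path, call. = FALSE)
    m <- tryCatch(Matrix::readMM(mtx), error = function(e)
      stop("malformed Matrix Market file '", mtx, "': ",
           conditionMessage(e), call. = FALSE))
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    features <- readLines(file.path(path, "features.tsv"))
    if (length(barcodes) != nrow(m)) {
      stop("barcodes.tsv has ", length(barcodes), " entries but the matrix ",
           "has ", nrow(m), " rows", call. = FALSE)
    }
    if (length(features) != ncol(m)) {
      stop("features.tsv has ", length(features), " entries but the matrix ",
           "has ", ncol(m), " columns", call. = FALSE)
    }
    if (anyDuplicated(features)) stop("duplicate gene ids in features.tsv",
                                      call. = FALSE)
    dimnames(m) <- list(barcodes, features)
    meta_path <- metadata %||% file.path(path, "cells.tsv")
    cells <- if (file.exists(meta_path)) {
      tibble::as_tibble(utils::read.delim(meta_path,
                                          stringsAsFactors = FALSE))
    } else {
      tibble::tibble(cell_id = barcodes)
    }
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path,
                                 call. = FALSE)
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (names(d)[1] != "cell_id") {
      stop("dense TSV must have 'cell_id' as its first column",
           call. = FALSE)
    }
    if (anyDuplicated(names(d)[-1])) stop("duplicate gene ids in dense TSV",
                                          call. = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$cell_id
    cells <- if (!is.null(metadata)) {
      tibble::as_tibble(utils::read.delim(metadata,
                                          stringsAsFactors = FALSE))
    } else {
      tibble::tibble(cell_id = d$cell_id)
    }
  }
  if (!all(rownames(m) == cells$cell_id)) {
    cells <- cells[match(rownames(m), cells$cell_id), , drop = FALSE]
    if (anyNA(cells$cell_id)) {
      stop("cell metadata does not cover all matrix cells", call. = FALSE)
    }
  }
  expr_dataset(m, cells, layer = layer)
}

#' Write an expression dataset as a dense TSV
#'
#' @param data An [expr_dataset()].
#' @param path Output file; first column `cell_id`, one column per gene.
#' @return `path`, invisibly.
#' @export
write_expression_dense <- function(data, path) {
  stopifnot(inherits(data, "expr_dataset"))
  d <- data.frame(cell_id = data$cells$cell_id,
                  as.matrix(data$values), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Duplicate genes within a set are dropped with a warning.
#'
#' @param path GMT file.
#' @return Named list of character vectors (attribute `"description"` on
#'   each element).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    genes <- parts[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", parts[1], "' contains duplicated genes; ",
              "deduplicated", call. = FALSE)
      genes <- unique(genes)
    }
    attr(genes, "description") <- parts[2]
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors; an optional `"description"`
#'   attribute per element becomes the second GMT field.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a TWAS fixture as three TSV files
#'
#' `weights.tsv` (gene, snp, weight), `ld.tsv` (square correlation matrix,
#' header and first column carrying SNP ids) and `gwas.tsv` (snp, z).
#'
#' @param fixture A [simulate_twas_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_twas_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fixture$weights, file.path(dir, "weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- as.matrix(fixture$ld)
  utils::write.table(data.frame(snp = rownames(ld), ld,
                                check.names = FALSE),
                     file.path(dir, "ld.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fixture$gwas, file.path(dir, "gwas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a TWAS fixture from its three TSV files
#'
#' @param dir Directory holding `weights.tsv`, `ld.tsv`, `gwas.tsv`.
#' @return A list of class `twas_fixture` (without truth labels).
#' @export
read_twas_fixture <- function(dir) {
  weights <- tibble::as_tibble(
    utils::read.delim(file.path(dir, "weights.tsv"),
                      stringsAsFactors = FALSE))
  ld_df <- utils::read.delim(file.path(dir, "ld.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
  ld <- as.matrix(ld_df[, -1, drop = FALSE])
  rownames(ld) <- ld_df$snp
  gwas <- tibble::as_tibble(
    utils::read.delim(file.path(dir, "gwas.tsv"),
                      stringsAsFactors = FALSE))
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8))) {
    stop("LD matrix read from ld.tsv is not symmetric", call. = FALSE)
  }
  structure(
    list(weights = weights,
         ld = methods::as(ld, "CsparseMatrix"),
         gwas = gwas, truth_causal_genes = NULL, params = NULL),
    class = "twas_fixture"
  )
}
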