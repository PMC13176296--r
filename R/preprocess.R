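#' Quality-control filter on detected genes and mitochondrial fraction
#'
#' Retains cells with `min_genes <= n_genes_detected <= max_genes` and
#' `pct_mito <= max_mito`. Boundaries are inclusive: the defaults drop cells
#' with fewer than 200 or more than 6000 detected genes, or more than 15%
#' mitochondrial counts, so 200, 6000 and 0.15 themselves survive.
#'
#' @param data An [expr_dataset()] with `n_genes_detected` and `pct_mito`
#'   cell covariates.
#' @param min_genes,max_genes Detected-gene bounds.
#' @param max_mito Maximum mitochondrial fraction.
#' @return The filtered `expr_dataset`; attribute `"qc_report"` holds a
#'   tibble of cells in/out per criterion.
#' @export
qc_filter <- function(data, min_genes = 200, max_genes = 6000,
                      max_mito = 0.15) {
  stopifnot(inherits(data, "expr_dataset"))
  for (col in c("n_genes_detected", "pct_mito")) {
    if (!col %in% names(data$cells)) {
      stop("QC covariate column '", col, "' is missing from cell metadata",
           call. = FALSE)
    }
  }
  det <- data$cells$n_genes_detected
  mito <- data$cells$pct_mito
  pass_low <- det >= min_genes
  pass_high <- det <= max_genes
  pass_mito <- mito <= max_mito
  keep <- pass_low & pass_high & pass_mito
  out <- subset_cells(data, cells = which(keep))
  attr(out, "qc_report") <- tibble::tibble(
    criterion = c("min_genes", "max_genes", "max_mito", "all"),
    threshold = c(min_genes, max_genes, max_mito, NA),
    n_fail = c(sum(!pass_low), sum(!pass_high), sum(!pass_mito), sum(!keep)),
    n_pass = nrow(data$values) - c(sum(!pass_low), sum(!pass_high),
                                   sum(!pass_mito), sum(!keep))
  )
  out
}

#' Library-size log-normalization
#'
#' Per cell, `value -> ln(1 + scale_total * value / cell_total)` — counts are
#' scaled to a common total and log1p-transformed. Within-cell expression
#' ranks are preserved.
#'
#' @param data An [expr_dataset()] carrying raw counts.
#' @param scale_total Target per-cell total after scaling.
#' @return The `expr_dataset` with layer `"lognorm"`.
#' @export
lognormalize <- function(data, scale_total = 1e4) {
  stopifnot(inherits(data, "expr_dataset"))
  if (data$layer != "counts") {
    stop("lognormalize expects the raw-count layer", call. = FALSE)
  }
  totals <- Matrix::rowSums(data$values)
  if (any(totals == 0)) {
    stop("cells with zero total counts present (",
         sum(totals == 0), "); remove them with qc_filter first",
         call. = FALSE)
  }
  m <- data$values
  m@x <- m@x * (scale_total / totals)[m@i + 1L]
  m@x <- log1p(m@x)
  out <- data
  out$values <- m
  out$layer <- "lognorm"
  out
}

#' Select highly variable genes
#'
#' Genes ranked by the variance of their log-normalized expression across
#' cells (descending), with gene id as the deterministic tiebreak; the top
#' `n` are returned.
#'
#' @param data An [expr_dataset()], log-normalized.
#' @param n Number of genes to return.
#' @return Character vector of `n` gene ids, ranked.
#' @export
select_hvg <- function(data, n = 2000) {
  stopifnot(inherits(data, "expr_dataset"))
  if (n > length(data$genes)) {
    stop("n (", n, ") exceeds the number of genes (", length(data$genes),
         ")", call. = FALSE)
  }
  m <- data$values
  nc <- nrow(m)
  mu <- Matrix::colMeans(m)
  v <- (Matrix::colSums(m^2) - nc * mu^2) / (nc - 1)
  ord <- order(-v, data$genes)
  data$genes[ord][seq_len(n)]
}

#' PCA embedding of selected genes
#'
#' The selected genes are standardized (zero mean, unit variance, values
#' clipped at +/-10) and the top `d` principal components are computed. Each
#' component's sign is fixed so that its largest-magnitude gene loading is
#' positive.
#'
#' @param data An [expr_dataset()], log-normalized.
#' @param genes Gene ids to embed (e.g. from [select_hvg()]).
#' @param d Number of components.
#' @return Cell x d matrix of coordinates; attribute `"sdev"` carries the
#'   component standard deviations and `"rotation"` the (sign-fixed)
#'   loadings.
#' @export
pca_embed <- function(data, genes = NULL, d = 50) {
  stopifnot(inherits(data, "expr_dataset"))
  if (is.null(genes)) genes <- data$genes
  if (!all(genes %in% data$genes)) stop("unknown gene in 'genes'",
                                        call. = FALSE)
  if (d > min(nrow(data$values), length(genes))) {
    stop("d (", d, ") exceeds min(cells, genes)", call. = FALSE)
  }
  x <- as.matrix(data$values[, genes, drop = FALSE])
  x <- scale(x)
  x[is.na(x)] <- 0  # zero-variance genes carry no signal
  x[x > 10] <- 10
  x[x < -10] <- -10
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = d)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, "*")
  rownames(coords) <- data$cells$cell_id
  attr(coords, "sdev") <- pc$sdev[seq_len(d)]
  attr(coords, "rotation") <- sweep(rot, 2, flip, "*")
  coords
}
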