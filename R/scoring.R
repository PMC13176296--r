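#' @name activity-scores
#' @title Per-cell gene-set activity scores
#'
#' @description Five independent per-cell statistics of the composite
#' activity of a gene set: an expression-matched module score
#' ([score_module_mean()]), the area under the gene-set recovery curve in the
#' top-ranked genes ([score_aucell()]), a Mann-Whitney-U rank score against
#' the clipped complement ([score_ucell()]), the centered mean normalized
#' rank ([score_singscore()]), and an integrated weighted Kolmogorov-Smirnov
#' running sum ([score_ssgsea()]). All five operate on the log-normalized
#' layer; the rank-based four are invariant under strictly monotone
#' transforms of expression. Ranking ties are always broken by gene id so
#' results are deterministic.
NULL

# Intersect a gene set with the measured genes; error when empty.
resolve_gene_set <- function(data, gene_set) {
  gene_set <- unique(as.character(gene_set))
  present <- intersect(gene_set, data$genes)
  if (length(present) == 0) {
    stop("gene set has no genes in the dataset; missing: ",
         paste(utils::head(setdiff(gene_set, data$genes), 10),
               collapse = ", "),
         call. = FALSE)
  }
  present
}

check_lognorm <- function(data) {
  stopifnot(inherits(data, "expr_dataset"))
  if (data$layer != "lognorm") {
    stop("scoring expects the log-normalized layer; run lognormalize()",
         call. = FALSE)
  }
}

# Descending within-cell ranks (1 = highest expression), ties broken by the
# alphabetical order of gene ids: columns are ranked in sorted-gene-id order
# with ties.method = "first", so the first (alphabetically earliest) gene of
# a tie wins. Returns a cells x genes integer matrix.
rank_desc_matrix <- function(data) {
  m <- dense_values(data)
  ord <- order(colnames(m))
  r2 <- matrixStats::rowRanks(-m[, ord, drop = FALSE],
                              ties.method = "first")
  r <- r2[, order(ord), drop = FALSE]
  dimnames(r) <- dimnames(m)
  r
}

#' Module score: set mean minus expression-matched control mean
#'
#' Genes are binned by average expression across cells; for every set gene,
#' `n_ctrl` control genes are sampled (seeded) from the non-set genes of its
#' bin (falling back to the whole bin when no non-set gene is available). The
#' score is the mean expression of set genes minus the mean over all sampled
#' control genes.
#'
#' @param data Log-normalized [expr_dataset()].
#' @param gene_set Character vector of gene ids.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes sampled per set gene.
#' @param seed Integer seed for control sampling.
#' @return Named per-cell numeric vector.
#' @export
score_module_mean <- function(data, gene_set, n_bins = 24, n_ctrl = 100,
                              seed = 1L) {
  check_lognorm(data)
  set_genes <- resolve_gene_set(data, gene_set)
  set.seed(as.integer(seed))
  avg <- Matrix::colMeans(data$values)
  n_bins <- min(n_bins, length(avg))
  bin <- as.integer(cut(rank(avg, ties.method = "first"), breaks = n_bins))
  names(bin) <- data$genes
  ctrl <- unlist(lapply(set_genes, function(g) {
    pool <- data$genes[bin == bin[g]]
    cand <- setdiff(pool, set_genes)
    if (length(cand) == 0) cand <- pool
    if (length(cand) >= n_ctrl) sample(cand, n_ctrl)
    else sample(cand, n_ctrl, replace = TRUE)
  }))
  set_mean <- Matrix::rowMeans(data$values[, set_genes, drop = FALSE])
  tab <- table(ctrl)  # control genes keep their sampling multiplicity
  ctrl_mean <- as.numeric(data$values[, names(tab), drop = FALSE] %*%
                            as.numeric(tab)) / length(ctrl)
  out <- as.numeric(set_mean - ctrl_mean)
  names(out) <- data$cells$cell_id
  out
}

#' AUCell-type score: area under the set-recovery curve
#'
#' Per cell, genes are ranked by expression (descending, gene-id tiebreak);
#' the score is the area under the step curve counting recovered set genes up
#' to rank `ceiling(top_fraction * G)`, normalized to \[0, 1\] by the maximal
#' achievable area.
#'
#' @inheritParams score_module_mean
#' @param top_fraction Fraction of the ranking over which recovery is
#'   integrated.
#' @param .ranks Internal: precomputed [rank_desc_matrix] to avoid re-ranking.
#' @return Named per-cell numeric vector in \[0, 1\].
#' @export
score_aucell <- function(data, gene_set, top_fraction = 0.05,
                         .ranks = NULL) {
  check_lognorm(data)
  set_genes <- resolve_gene_set(data, gene_set)
  G <- length(data$genes)
  top <- ceiling(top_fraction * G)
  if (top < 1) stop("top rank is < 1; increase top_fraction", call. = FALSE)
  r <- (.ranks %||% rank_desc_matrix(data))[, set_genes, drop = FALSE]
  m <- min(length(set_genes), top)
  max_area <- sum(top - seq_len(m) + 1)
  contrib <- pmax(top - r + 1, 0)
  out <- rowSums(contrib) / max_area
  names(out) <- data$cells$cell_id
  out
}

#' UCell-type score: Mann-Whitney U of clipped set-gene ranks
#'
#' Per cell, descending ranks are clipped at `max_rank`; with `U'` the
#' Mann-Whitney U statistic of the set genes against the clipped complement
#' (`U' = sum(clipped set ranks) - n_s(n_s+1)/2`), the score is
#' `1 - U' / (n_s * (max_rank - n_s))`.
#'
#' @inheritParams score_module_mean
#' @param max_rank Rank clip; genes ranked beyond it count as `max_rank`.
#' @param .ranks Internal: precomputed [rank_desc_matrix] to avoid re-ranking.
#' @return Named per-cell numeric vector (approximately \[0, 1\]).
#' @export
score_ucell <- function(data, gene_set, max_rank = 1500, .ranks = NULL) {
  check_lognorm(data)
  set_genes <- resolve_gene_set(data, gene_set)
  ns <- length(set_genes)
  if (ns >= max_rank) {
    stop("gene set size (", ns, ") must be smaller than max_rank (",
         max_rank, ")", call. = FALSE)
  }
  r <- (.ranks %||% rank_desc_matrix(data))[, set_genes, drop = FALSE]
  r <- pmin(r, max_rank)
  u <- rowSums(r) - ns * (ns + 1) / 2
  out <- 1 - u / (ns * (max_rank - ns))
  names(out) <- data$cells$cell_id
  out
}

#' singscore-type score: centered mean normalized rank
#'
#' Per cell, genes are rank-normalized ascending to `(rank - 0.5) / G`; the
#' score is the mean normalized rank of the set genes minus 0.5 (its
#' expectation under no enrichment), so the range is symmetric about 0.
#'
#' @inheritParams score_module_mean
#' @param .ranks Internal: precomputed [rank_desc_matrix] to avoid re-ranking.
#' @return Named per-cell numeric vector in (-0.5, 0.5).
#' @export
score_singscore <- function(data, gene_set, .ranks = NULL) {
  check_lognorm(data)
  set_genes <- resolve_gene_set(data, gene_set)
  G <- length(data$genes)
  r_desc <- (.ranks %||% rank_desc_matrix(data))[, set_genes, drop = FALSE]
  r_asc <- G - r_desc + 1
  out <- rowMeans((r_asc - 0.5) / G) - 0.5
  names(out) <- data$cells$cell_id
  out
}

#' ssGSEA-type score: integrated weighted KS running sum
#'
#' Per cell, genes are ordered by expression descending; walking down the
#' list, the running sum increments by the set gene's rank weight
#' `(G - position + 1)^alpha`, normalized over the set, and decrements by
#' `1 / (G - n_s)` at non-set genes. The score is the sum of the running-sum
#' values over all positions (the integrated enrichment), positive when the
#' set concentrates at the top.
#'
#' @inheritParams score_module_mean
#' @param alpha Rank-weight exponent; `alpha = 0` gives the unweighted KS
#'   running sum.
#' @param .ranks Internal: precomputed [rank_desc_matrix] to avoid re-ranking.
#' @return Named per-cell numeric vector.
#' @export
score_ssgsea <- function(data, gene_set, alpha = 0.25, .ranks = NULL) {
  check_lognorm(data)
  set_genes <- resolve_gene_set(data, gene_set)
  G <- length(data$genes)
  ns <- length(set_genes)
  if (ns >= G) stop("gene set must leave a non-empty complement",
                    call. = FALSE)
  r <- .ranks %||% rank_desc_matrix(data)
  in_set <- data$genes %in% set_genes
  # integrated running sum: sum_i step_i * (G - pos_i + 1)
  w_set <- (G - r[, in_set, drop = FALSE] + 1)
  inc <- rowSums(w_set^alpha * w_set) / rowSums(w_set^alpha)
  w_out <- (G - r[, !in_set, drop = FALSE] + 1)
  dec <- rowSums(w_out) / (G - ns)
  out <- as.numeric(inc - dec)
  names(out) <- data$cells$cell_id
  out
}

#' Normalize a raw score panel to \[0, 1\] per column
#'
#' Each column is z-scored (zero mean, unit variance) and then min-max
#' rescaled to \[0, 1\]. Because z-scoring is affine, the composition equals
#' plain min-max on non-constant columns; both steps are kept for fidelity to
#' the described procedure. Constant columns map to 0.5 so they are neutral
#' in the composite sum.
#'
#' @param raw Cell x score numeric matrix.
#' @return Matrix of the same shape with columns in \[0, 1\].
#' @export
normalize_panel <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) stop("need at least 2 cells to normalize",
                          call. = FALSE)
  apply(raw, 2, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0.5, length(x)))
    z <- (x - mean(x)) / s
    (z - min(z)) / (max(z) - min(z))
  })
}

#' Composite activity score
#'
#' Row sums of the normalized panel; with five scores the range is \[0, 5\].
#'
#' @param normalized Cell x score matrix with entries in \[0, 1\].
#' @return Named per-cell numeric vector.
#' @export
composite_score <- function(normalized) {
  normalized <- as.matrix(normalized)
  if (any(normalized < -1e-8 | normalized > 1 + 1e-8)) {
    stop("normalized panel entries must lie in [0, 1]", call. = FALSE)
  }
  rowSums(normalized)
}

#' Spearman correlation between the five raw scores
#'
#' @param raw Cell x score numeric matrix (>= 3 cells).
#' @return Symmetric correlation matrix with unit diagonal; entries involving
#'   a constant column are `NA`.
#' @export
score_correlation <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 3) stop("need at least 3 cells", call. = FALSE)
  cc <- suppressWarnings(cor(raw, method = "spearman"))
  diag(cc) <- 1
  cc
}

#' Full activity panel: five scores, normalization, composite
#'
#' Runs all five scoring statistics on a log-normalized dataset, normalizes
#' each to \[0, 1\] and sums them into the composite activity score
#' (`scoring`, in \[0, 5\]).
#'
#' @inheritParams score_module_mean
#' @param n_bins,n_ctrl Module-score control-matching parameters.
#' @param top_fraction AUCell-type recovery window.
#' @param max_rank UCell-type rank clip.
#' @param alpha ssGSEA-type rank-weight exponent.
#' @return A tibble of class `activity_panel`: `cell_id`, the five raw
#'   scores, their normalized versions (`norm_` prefix) and `scoring`.
#' @export
score_activity <- function(data, gene_set, n_bins = 24, n_ctrl = 100,
                           top_fraction = 0.05, max_rank = 1500,
                           alpha = 0.25, seed = 1L) {
  check_lognorm(data)
  max_rank <- min(max_rank, length(data$genes))
  ranks <- rank_desc_matrix(data)  # shared by the four rank-based scores
  raw <- cbind(
    module_mean = score_module_mean(data, gene_set, n_bins, n_ctrl, seed),
    aucell = score_aucell(data, gene_set, top_fraction, .ranks = ranks),
    ucell = score_ucell(data, gene_set, max_rank, .ranks = ranks),
    singscore = score_singscore(data, gene_set, .ranks = ranks),
    ssgsea = score_ssgsea(data, gene_set, alpha, .ranks = ranks)
  )
  norm <- normalize_panel(raw)
  out <- tibble::tibble(cell_id = data$cells$cell_id)
  for (j in colnames(raw)) out[[j]] <- unname(raw[, j])
  for (j in colnames(norm)) out[[paste0("norm_", j)]] <- unname(norm[, j])
  out$scoring <- unname(composite_score(norm))
  class(out) <- c("activity_panel", class(out))
  out
}

score_names <- c("module_mean", "aucell", "ucell", "singscore", "ssgsea")

#' @export
tidy.activity_panel <- function(x, ...) {
  d <- tibble::as_tibble(x)
  raw <- tidyr::pivot_longer(d[, c("cell_id", score_names)],
                             -dplyr::all_of("cell_id"),
                             names_to = "score", values_to = "raw")
  norm <- d[, c("cell_id", paste0("norm_", score_names))]
  names(norm) <- sub("^norm_", "", names(norm))
  norm <- tidyr::pivot_longer(norm, -dplyr::all_of("cell_id"),
                              names_to = "score", values_to = "normalized")
  dplyr::left_join(raw, norm, by = c("cell_id", "score")) |>
    dplyr::left_join(d[, c("cell_id", "scoring")], by = "cell_id")
}

#' @export
glance.activity_panel <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    scoring_mean = mean(x$scoring),
    scoring_min = min(x$scoring),
    scoring_max = max(x$scoring)
  )
}

#' Density plot of the composite activity score
#'
#' @param object An [score_activity()] panel.
#' @param ... Unused.
#' @return A ggplot of the `scoring` distribution.
#' @export
autoplot.activity_panel <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$scoring)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "composite activity score", y = "density") +
    ggplot2::theme_minimal()
}
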