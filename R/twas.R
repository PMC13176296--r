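#' Gene-level TWAS association z-score from summary statistics
#'
#' The canonical summary-statistic TWAS test: for a gene with cis-SNP
#' expression weights `w`, GWAS z-scores `z` and SNP correlation (LD) matrix
#' `V`, the association statistic is `w'z / sqrt(w'Vw)`, standard normal under
#' the null.
#'
#' @param weights Per-SNP weight vector.
#' @param gwas_z Per-SNP GWAS z-scores, aligned to `weights`.
#' @param ld SNP correlation matrix, aligned to `weights`.
#' @param tol Predictive-variance tolerance below which the gene is
#'   untestable.
#' @return The z statistic, or `NA_real_` (untestable) when `w'Vw <= tol`.
#' @export
twas_zscore <- function(weights, gwas_z, ld, tol = 1e-12) {
  weights <- as.numeric(weights)
  gwas_z <- as.numeric(gwas_z)
  ld <- as.matrix(ld)
  p <- length(weights)
  if (length(gwas_z) != p || nrow(ld) != p || ncol(ld) != p) {
    stop("weights, gwas_z and ld must share the same SNP dimension",
         call. = FALSE)
  }
  v <- as.numeric(crossprod(weights, ld %*% weights))
  if (v <= tol) return(NA_real_)
  sum(weights * gwas_z) / sqrt(v)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH step-up with monotonicity enforcement; the output is returned
#' in the input order.
#'
#' @param pvalues Vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  n <- length(p)
  if (n == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

#' Run the TWAS scan over a summary-statistics fixture
#'
#' Computes the gene-level association z for every gene in the fixture,
#' two-sided normal p-values, BH-adjusted q-values across all testable genes,
#' and the significance flag at `q < alpha` (strict). Genes with degenerate
#' predictive variance are flagged untestable and excluded from multiple
#' testing (their q is `NA` and they are never significant).
#'
#' @param fixture A [simulate_twas_fixture()] result, or any list with
#'   `weights` (gene/snp/weight tibble), `ld` and `gwas` in the same layout.
#' @param alpha FDR threshold defining significance.
#' @return A tibble of class `twas_scan`: `gene`, `z`, `p`, `q`,
#'   `significant`, `testable`, ordered as in the fixture.
#' @export
twas_scan <- function(fixture, alpha = 0.05) {
  w <- fixture$weights
  stopifnot(all(c("gene", "snp", "weight") %in% names(w)))
  zvec <- setNames(fixture$gwas$z, fixture$gwas$snp)
  if (!all(w$snp %in% names(zvec))) {
    stop("weight table references SNPs missing from the GWAS table",
         call. = FALSE)
  }
  if (!all(w$snp %in% rownames(fixture$ld))) {
    stop("weight table references SNPs missing from the LD matrix",
         call. = FALSE)
  }
  genes <- unique(w$gene)
  by_gene <- split(w[c("snp", "weight")], factor(w$gene, levels = genes))
  z <- vapply(by_gene, function(tab) {
    snps <- tab$snp
    twas_zscore(tab$weight, zvec[snps],
                fixture$ld[snps, snps, drop = FALSE])
  }, numeric(1))
  res <- tibble::tibble(
    gene = genes,
    z = unname(z),
    p = 2 * pnorm(-abs(unname(z))),
    testable = is.finite(z)
  )
  res$q <- NA_real_
  res$q[res$testable] <- bh_adjust(res$p[res$testable])
  res$significant <- !is.na(res$q) & res$q < alpha
  res <- res[, c("gene", "z", "p", "q", "significant", "testable")]
  class(res) <- c("twas_scan", class(res))
  attr(res, "alpha") <- alpha
  res
}

#' Select the risk-gene set from a TWAS scan
#'
#' Genes with BH-adjusted `q < alpha` (strict inequality), ordered by q
#' ascending with gene id as the deterministic tiebreak.
#'
#' @param results A [twas_scan()] tibble (needs `gene` and `q`).
#' @param alpha FDR threshold.
#' @return Character vector of risk-gene ids.
#' @export
select_risk_genes <- function(results, alpha = 0.05) {
  stopifnot(all(c("gene", "q") %in% names(results)))
  hit <- !is.na(results$q) & results$q < alpha
  sel <- results[hit, , drop = FALSE]
  sel$gene[order(sel$q, sel$gene)]
}

#' @export
glance.twas_scan <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_testable = sum(x$testable),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' @export
tidy.twas_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(unclass(x)), character(0))])
}

#' Volcano-style plot of a TWAS scan
#'
#' @param object A [twas_scan()] result.
#' @param ... Unused.
#' @return A ggplot: gene index against z, significant genes highlighted.
#' @export
autoplot.twas_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$z,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "gene", y = "TWAS z",
                  colour = sprintf("q < %.2g", attr(object, "alpha") %||% 0.05)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
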