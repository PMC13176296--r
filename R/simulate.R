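#' Simulation configuration
#'
#' Parameters of the synthetic single-cell experiment: a two-group cohort
#' (case/control patients) in which a planted subpopulation of "active" cells
#' over-expresses a designated risk-gene set, with a small subset of signature
#' genes carrying a stronger effect. Defaults describe the emulated study
#' design: 10 case and 10 control patients, a 125-gene risk set containing a
#' 6-gene signature, and a higher prevalence of active cells in cases.
#'
#' @param n_patients_case,n_patients_control Number of patients per group.
#' @param cells_per_patient Cells drawn per patient.
#' @param n_genes Total genes simulated.
#' @param n_risk_genes Size of the planted risk-gene set.
#' @param n_signature_genes Risk genes given the stronger signature effect.
#' @param active_fraction_case,active_fraction_control Fraction of each
#'   patient's cells planted as active, by group.
#' @param effect_log2fc Log2 fold-change applied to risk genes in active cells.
#' @param signature_log2fc Log2 fold-change for signature genes in active
#'   cells (replaces, not stacks on, `effect_log2fc`).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param libsize_sigma Log-normal sd of per-cell library-size factors.
#' @param mito_mean,mito_sd Mean and sd of the simulated mitochondrial
#'   fraction covariate.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients_case = 10, n_patients_control = 10,
                       cells_per_patient = 200, n_genes = 2000,
                       n_risk_genes = 125, n_signature_genes = 6,
                       active_fraction_case = 0.35,
                       active_fraction_control = 0.15,
                       effect_log2fc = 1, signature_log2fc = 2,
                       nb_dispersion = 0.5, libsize_sigma = 0.3,
                       mito_mean = 0.05, mito_sd = 0.03, seed = 1L) {
  cfg <- list(
    n_patients_case = n_patients_case,
    n_patients_control = n_patients_control,
    cells_per_patient = cells_per_patient, n_genes = n_genes,
    n_risk_genes = n_risk_genes, n_signature_genes = n_signature_genes,
    active_fraction_case = active_fraction_case,
    active_fraction_control = active_fraction_control,
    effect_log2fc = effect_log2fc, signature_log2fc = signature_log2fc,
    nb_dispersion = nb_dispersion, libsize_sigma = libsize_sigma,
    mito_mean = mito_mean, mito_sd = mito_sd, seed = as.integer(seed)
  )
  counts <- c("n_patients_case", "n_patients_control", "cells_per_patient",
              "n_genes", "n_risk_genes", "n_signature_genes")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      stop("invalid configuration: '", f, "' must be a count >= 1",
           call. = FALSE)
    }
  }
  props <- c("active_fraction_case", "active_fraction_control",
             "mito_mean", "mito_sd")
  for (f in props) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop("invalid configuration: '", f, "' must be a proportion in [0, 1]",
           call. = FALSE)
    }
  }
  for (f in c("nb_dispersion", "libsize_sigma")) {
    if (cfg[[f]] <= 0) {
      stop("invalid configuration: '", f, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$n_signature_genes > cfg$n_risk_genes) {
    stop("invalid configuration: 'n_signature_genes' must not exceed ",
         "'n_risk_genes'", call. = FALSE)
  }
  if (cfg$n_risk_genes > cfg$n_genes) {
    stop("invalid configuration: 'n_risk_genes' must not exceed 'n_genes'",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a single-cell cohort with a planted active subpopulation
#'
#' Counts are drawn gene-wise negative-binomial: gene baseline means are
#' log-normal, each cell carries a log-normal library-size factor, and in
#' active cells the risk-gene means are multiplied by `2^effect_log2fc`
#' (signature genes by `2^signature_log2fc`). Active cells are assigned per
#' patient by a fixed quota, `round(active_fraction * cells_per_patient)`, so
#' the planted truth counts are exact. Detected-gene counts and a simulated
#' mitochondrial fraction are recorded as QC covariates.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `expression` (an [expr_dataset()]
#'   of raw counts), `truth_active_cells`, `truth_risk_genes`,
#'   `truth_signature_genes`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  base_mean <- rlnorm(config$n_genes, meanlog = log(0.2), sdlog = 1)
  names(base_mean) <- genes
  # risk genes mimic TWAS-testable genes: they carry expression weights in
  # the reference tissue, so they are drawn from the expressed (upper) half
  # of the baseline-mean distribution
  expressed <- genes[base_mean >= median(base_mean)]
  if (length(expressed) < config$n_risk_genes) {
    expressed <- genes[order(-base_mean)][seq_len(config$n_risk_genes)]
  }
  risk <- sort(sample(expressed, config$n_risk_genes))
  signature <- sort(sample(risk, config$n_signature_genes))

  patients <- c(sprintf("case%02d", seq_len(config$n_patients_case)),
                sprintf("ctrl%02d", seq_len(config$n_patients_control)))
  groups <- rep(c("case", "control"),
                c(config$n_patients_case, config$n_patients_control))
  n_cells <- length(patients) * config$cells_per_patient

  cells <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(n_cells)),
    patient = rep(patients, each = config$cells_per_patient),
    group = rep(groups, each = config$cells_per_patient),
    cell_type = "simulated"
  )

  # exact per-patient activity quota
  frac <- ifelse(cells$group == "case", config$active_fraction_case,
                 config$active_fraction_control)
  active <- logical(n_cells)
  for (p in patients) {
    idx <- which(cells$patient == p)
    quota <- round(frac[idx[1]] * length(idx))
    if (quota > 0) active[sample(idx, quota)] <- TRUE
  }

  lib <- rlnorm(n_cells, meanlog = 0, sdlog = config$libsize_sigma)

  fc <- rep(1, config$n_genes)
  names(fc) <- genes
  fc[risk] <- 2^config$effect_log2fc
  fc[signature] <- 2^config$signature_log2fc

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = n_cells, ncol = config$n_genes,
                   dimnames = list(cells$cell_id, genes))
  for (j in seq_len(config$n_genes)) {
    mu <- base_mean[j] * lib
    if (fc[j] != 1) mu[active] <- mu[active] * fc[j]
    counts[, j] <- rnbinom(n_cells, size = size, mu = mu)
  }

  cells$n_genes_detected <- as.integer(rowSums(counts > 0))
  cells$pct_mito <- pmin(1, pmax(0, rnorm(n_cells, config$mito_mean,
                                          config$mito_sd)))
  cells$truth_active <- active

  structure(
    list(
      expression = expr_dataset(counts, cells, layer = "counts"),
      truth_active_cells = cells$cell_id[active],
      truth_risk_genes = risk,
      truth_signature_genes = signature,
      config = config
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$expression$values), " cells, ",
      length(x$truth_risk_genes), " risk genes (",
      length(x$truth_signature_genes), " signature), ",
      length(x$truth_active_cells), " active cells\n", sep = "")
  invisible(x)
}

# AR(1) correlation block, rho^|i-j|; PSD for |rho| < 1.
ar1_block <- function(k, rho) {
  rho^abs(outer(seq_len(k), seq_len(k), "-"))
}

#' Simulate a TWAS summary-statistics fixture
#'
#' Builds per-gene cis-SNP weight vectors, a block-diagonal AR(1) LD matrix
#' (one block per gene), and GWAS per-SNP z-scores drawn multivariate normal
#' under that LD. For planted causal genes the z-score mean is shifted along
#' the direction `LD %*% w / sqrt(w' LD w)` scaled by `causal_z_shift`, so the
#' gene-level association statistic has expectation `causal_z_shift`.
#'
#' @param n_genes Number of genes in the fixture.
#' @param snps_per_gene cis-SNPs per gene (one LD block each).
#' @param n_causal Number of planted causal genes.
#' @param causal_z_shift Expected gene-level z for causal genes.
#' @param rho AR(1) correlation within each LD block; must be in (-1, 1).
#' @param seed Integer seed.
#' @return A list of class `twas_fixture`: `weights` (tibble gene/snp/weight),
#'   `ld` (sparse symmetric SNP correlation matrix, unit diagonal), `gwas`
#'   (tibble snp/z), `truth_causal_genes`.
#' @export
simulate_twas_fixture <- function(n_genes = 200, snps_per_gene = 5,
                                  n_causal = 10, causal_z_shift = 6,
                                  rho = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1, snps_per_gene >= 1)
  if (n_causal > n_genes) stop("n_causal must not exceed n_genes",
                               call. = FALSE)
  if (abs(rho) >= 1) {
    stop("requested LD correlation is not positive semi-definite ",
         "(|rho| must be < 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(n_genes))
  causal <- sort(sample(genes, n_causal))
  R <- ar1_block(snps_per_gene, rho)
  Rchol <- chol(R)

  snp_ids <- as.vector(vapply(genes, function(g)
    sprintf("%s_snp%02d", g, seq_len(snps_per_gene)),
    character(snps_per_gene)))

  w_list <- vector("list", n_genes)
  z <- numeric(n_genes * snps_per_gene)
  for (i in seq_len(n_genes)) {
    w <- rnorm(snps_per_gene)
    w_list[[i]] <- w
    mu <- rep(0, snps_per_gene)
    if (genes[i] %in% causal) {
      mu <- causal_z_shift * as.vector(R %*% w) /
        sqrt(as.numeric(crossprod(w, R %*% w)))
    }
    idx <- (i - 1) * snps_per_gene + seq_len(snps_per_gene)
    z[idx] <- mu + as.vector(crossprod(Rchol, rnorm(snps_per_gene)))
  }

  ld <- Matrix::bdiag(rep(list(R), n_genes))
  dimnames(ld) <- list(snp_ids, snp_ids)

  structure(
    list(
      weights = tibble::tibble(
        gene = rep(genes, each = snps_per_gene),
        snp = snp_ids,
        weight = unlist(w_list)
      ),
      ld = ld,
      gwas = tibble::tibble(snp = snp_ids, z = z),
      truth_causal_genes = causal,
      params = list(n_genes = n_genes, snps_per_gene = snps_per_gene,
                    n_causal = n_causal, causal_z_shift = causal_z_shift,
                    rho = rho, seed = as.integer(seed))
    ),
    class = "twas_fixture"
  )
}

#' Fixed QC-threshold ladder fixture
#'
#' A deterministic 30-cell dataset whose detected-gene counts span
#' \{100, 199, 200, 300, 6000, 6001\} and mitochondrial fractions span
#' \{0, 0.10, 0.15, 0.151, 0.30\}, fully crossed, for exercising QC boundary
#' semantics.
#'
#' @return An [expr_dataset()] of 30 cells.
#' @export
qc_ladder_fixture <- function() {
  det <- c(100L, 199L, 200L, 300L, 6000L, 6001L)
  mito <- c(0, 0.10, 0.15, 0.151, 0.30)
  grid <- expand.grid(n_genes_detected = det, pct_mito = mito,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  cells <- tibble::tibble(
    cell_id = sprintf("ladder_%d_%0.3f", grid$n_genes_detected,
                      grid$pct_mito),
    patient = "ladderP1", group = "control", cell_type = "ladder",
    n_genes_detected = grid$n_genes_detected,
    pct_mito = grid$pct_mito
  )
  # small deterministic count matrix; QC consumes only the covariates
  genes <- sprintf("g%05d", 1:10)
  vals <- matrix(((seq_len(n * 10) * 7L) %% 11L), nrow = n,
                 dimnames = list(cells$cell_id, genes))
  expr_dataset(vals, cells, layer = "counts")
}
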