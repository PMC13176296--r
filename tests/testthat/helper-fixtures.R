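# Shared builders for small deterministic fixtures.

# Dense cell x gene matrix wrapped as a log-normalized expr_dataset, with
# minimal metadata. Values are taken as-is (rank-based scores only care about
# order), so toy matrices can be written by hand.
toy_lognorm <- function(values, patient = NULL, group = NULL,
                        cell_type = "toy") {
  n <- nrow(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cell%03d", seq_len(n))
  }
  cells <- tibble::tibble(
    cell_id = rownames(values),
    patient = patient %||% rep("p1", n),
    group = group %||% rep("control", n),
    cell_type = cell_type,
    n_genes_detected = as.integer(rowSums(values > 0)),
    pct_mito = 0
  )
  expr_dataset(values, cells, layer = "lognorm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small planted simulation used across modules; light enough for unit tests.
small_sim <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_patients_case = 3, n_patients_control = 3,
         cells_per_patient = 80, n_genes = 400, n_risk_genes = 25,
         n_signature_genes = 4, seed = seed),
    list(...))
  simulate_dataset(do.call(sim_config, args))
}

# QC settings matched to the small simulation's gene count.
small_qc <- function(data) qc_filter(data, min_genes = 10, max_genes = 1e6,
                                     max_mito = 1)

# A ready classification task from a small planted simulation.
small_task <- function(seed = 1L, ...) {
  s <- small_sim(seed = seed, ...)
  d <- lognormalize(small_qc(s$expression))
  panel <- score_activity(d, s$truth_risk_genes, max_rank = 300, seed = seed)
  strata <- stratify_quartiles(panel)
  list(task = build_task(d, strata, s$truth_risk_genes), sim = s,
       data = d, panel = panel, strata = strata)
}
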