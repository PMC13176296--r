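#' Pipeline configuration
#'
#' Collects every stage's parameters, the input sources (a simulation
#' configuration and TWAS fixture parameters, or paths to on-disk inputs)
#' and the global seed. All stage seeds are derived from `seed`.
#'
#' @param sim A [sim_config()] used when no expression paths are given.
#' @param twas A list of [simulate_twas_fixture()] arguments used when no
#'   fixture paths are given, or `NULL` to skip the TWAS stage (then
#'   `gene_set_path` must name a GMT file with the risk set).
#' @param expression_path,metadata_path,fixture_dir,gene_set_path Optional
#'   on-disk inputs overriding simulation.
#' @param qc List: `min_genes`, `max_genes`, `max_mito`.
#' @param scale_total Log-normalization scale.
#' @param scoring List of [score_activity()] parameters.
#' @param stratify_scope `"cell_type"` or `"all"`.
#' @param select Named per-method parameter lists for [consensus_select()].
#' @param benchmark List: `train_fraction`, `inner_folds`, `outer_folds`.
#' @param seed Global integer seed.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            twas = list(n_genes = 200, snps_per_gene = 5,
                                        n_causal = 10, causal_z_shift = 6),
                            expression_path = NULL, metadata_path = NULL,
                            fixture_dir = NULL, gene_set_path = NULL,
                            qc = list(min_genes = 200, max_genes = 6000,
                                      max_mito = 0.15),
                            scale_total = 1e4,
                            scoring = list(n_bins = 24, n_ctrl = 100,
                                           top_fraction = 0.05,
                                           max_rank = 1500, alpha = 0.25),
                            stratify_scope = "cell_type",
                            select = list(),
                            benchmark = list(train_fraction = 0.8,
                                             inner_folds = 5,
                                             outer_folds = 10),
                            seed = 1L, out_dir = tempfile("twascore_run_")) {
  structure(
    list(sim = sim, twas = twas, expression_path = expression_path,
         metadata_path = metadata_path, fixture_dir = fixture_dir,
         gene_set_path = gene_set_path, qc = qc,
         scale_total = scale_total, scoring = scoring,
         stratify_scope = stratify_scope, select = select,
         benchmark = benchmark, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  message("[twascore] stage '", name, "' ...")
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message("[twascore] stage '", name, "' done in ",
          sprintf("%.1fs", as.numeric(difftime(Sys.time(), t0,
                                               units = "secs"))))
  out
}

write_tsv_plain <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full activity-scoring pipeline
#'
#' Executes, in order: the TWAS scan defining the risk-gene set, QC
#' filtering, log-normalization, the five-score activity panel and composite
#' score, quartile stratification with Ro/e group enrichment, the
#' seven-selector consensus signature, and the patient-grouped benchmark
#' (nested CV, held-out test ROC/PR, LOPO-CV on the consensus signature).
#' Every intermediate table is written to `config$out_dir` along with a
#' manifest recording the seed and parameters.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `twascore_pipeline` with all stage
#'   results (`risk_genes`, `twas`, `data`, `panel`, `strata`, `roe`,
#'   `task`, `selection`, `split`, `benchmark`, `test_eval`, `lopo`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- TWAS stage: define the risk-gene set ---------------------------------
  scan <- NULL
  if (!is.null(config$fixture_dir)) {
    fixture <- run_stage("twas", read_twas_fixture(config$fixture_dir))
    scan <- twas_scan(fixture)
    risk_genes <- select_risk_genes(scan)
  } else if (!is.null(config$gene_set_path)) {
    sets <- run_stage("gene_set", read_gmt(config$gene_set_path))
    risk_genes <- as.character(sets[[1]])
  } else if (!is.null(config$twas)) {
    fixture <- run_stage("twas", do.call(
      simulate_twas_fixture, c(config$twas, list(seed = seed + 1L))))
    scan <- twas_scan(fixture)
    risk_genes <- select_risk_genes(scan)
  } else {
    risk_genes <- NULL
  }
  if (!is.null(scan)) {
    write_tsv_plain(tibble::as_tibble(scan),
                    file.path(config$out_dir, "twas_scan.tsv"))
  }

  # --- expression data ------------------------------------------------------
  truth <- NULL
  if (!is.null(config$expression_path)) {
    data <- run_stage("read_expression",
                      read_expression(config$expression_path,
                                      metadata = config$metadata_path))
  } else {
    simd <- run_stage("simulate", {
      cfg <- config$sim
      cfg$seed <- seed
      simulate_dataset(cfg)
    })
    data <- simd$expression
    truth <- simd
    # when the TWAS stage ran on a synthetic fixture its gene universe is
    # disjoint from the expression genes; the planted risk set is the
    # simulated analogue of the significant TWAS genes
    if (is.null(config$expression_path) && is.null(config$gene_set_path)) {
      risk_genes <- simd$truth_risk_genes
    }
  }
  if (is.null(risk_genes) || !length(risk_genes)) {
    stop("pipeline stage 'risk_genes' failed: no risk-gene set available",
         call. = FALSE)
  }
  writeLines(risk_genes, file.path(config$out_dir, "risk_genes.txt"))
  write_gmt(list(risk_genes = risk_genes),
            file.path(config$out_dir, "risk_genes.gmt"))

  # --- QC + normalization ---------------------------------------------------
  data <- run_stage("qc_filter", do.call(qc_filter, c(list(data), config$qc)))
  write_tsv_plain(attr(data, "qc_report"),
                  file.path(config$out_dir, "qc_report.tsv"))
  data <- run_stage("lognormalize", lognormalize(data, config$scale_total))

  # --- activity scoring -----------------------------------------------------
  panel <- run_stage("score_activity", do.call(
    score_activity,
    c(list(data, risk_genes), config$scoring, list(seed = seed + 2L))))
  write_tsv_plain(tibble::as_tibble(panel),
                  file.path(config$out_dir, "activity_panel.tsv"))

  # --- stratification + Ro/e ------------------------------------------------
  strata <- run_stage("stratify",
                      stratify_activity(panel, cell_info(data),
                                        scope = config$stratify_scope))
  lab_out <- dplyr::left_join(cell_info(data), strata$labels, by = "cell_id")
  write_tsv_plain(lab_out, file.path(config$out_dir, "cell_strata.tsv"))
  roe <- run_stage("roe", roe_enrichment(strata, cell_info(data)))
  write_tsv_plain(tibble::as_tibble(roe),
                  file.path(config$out_dir, "roe.tsv"))

  # --- consensus signature --------------------------------------------------
  task <- run_stage("build_task", build_task(data, strata, risk_genes))
  selection <- run_stage("consensus_select",
                         consensus_select(task, params = config$select,
                                          seed = seed + 3L))
  jsonlite::write_json(
    list(selections = lapply(selection$selections, function(d)
      d[, c("feature", "importance", "rank")]),
      consensus = selection$consensus, seed = selection$seed),
    file.path(config$out_dir, "selection_report.json"),
    auto_unbox = TRUE, digits = NA)
  writeLines(selection$consensus,
             file.path(config$out_dir, "consensus_signature.txt"))

  # --- benchmark ------------------------------------------------------------
  bm <- config$benchmark
  split <- run_stage("split",
                     patient_grouped_split(task, bm$train_fraction,
                                           seed = seed + 4L))
  benchmark <- run_stage("nested_cv", nested_cv_benchmark(
    split$train, inner_folds = bm$inner_folds,
    outer_folds = bm$outer_folds, seed = seed + 5L))
  learners <- default_learners()
  best <- learners[[benchmark$best_learner]]
  test_eval <- run_stage("test_eval", evaluate_model(
    split$train, split$test, best,
    hp = benchmark$best_params[[benchmark$best_learner]],
    seed = seed + 6L))
  lopo <- run_stage("lopo_cv", lopo_cv(task, selection$consensus,
                                       seed = seed + 7L))
  write_tsv_plain(benchmark$fold_aucs,
                  file.path(config$out_dir, "benchmark_fold_aucs.tsv"))
  write_tsv_plain(test_eval$eval$roc, file.path(config$out_dir, "roc.tsv"))
  write_tsv_plain(test_eval$eval$pr, file.path(config$out_dir, "pr.tsv"))
  write_tsv_plain(lopo$per_patient,
                  file.path(config$out_dir, "lopo_aucs.tsv"))
  jsonlite::write_json(
    list(best_learner = benchmark$best_learner,
         mean_auc = setNames(as.list(benchmark$summary$mean_auc),
                             benchmark$summary$learner),
         test_auc = test_eval$eval$auc,
         lopo_median_auc = lopo$median_auc,
         achieved_train_fraction = split$achieved_fraction),
    file.path(config$out_dir, "eval_report.json"),
    auto_unbox = TRUE, digits = NA)

  # --- manifest -------------------------------------------------------------
  strip_class <- function(x) if (is.list(x)) lapply(unclass(x), strip_class)
                             else x
  cfg_plain <- strip_class(unclass(config))
  cfg_plain$out_dir <- NULL  # path-free so equal-seed runs match byte-wise
  manifest <- list(
    package = "twascore",
    version = as.character(utils::packageVersion("twascore")),
    seed = seed,
    config = cfg_plain,
    outputs = sort(list.files(config$out_dir))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(structure(
    list(risk_genes = risk_genes, twas = scan, data = data, truth = truth,
         panel = panel, strata = strata, roe = roe, task = task,
         selection = selection, split = split, benchmark = benchmark,
         test_eval = test_eval, lopo = lopo, out_dir = config$out_dir),
    class = "twascore_pipeline"
  ))
}

#' @export
print.twascore_pipeline <- function(x, ...) {
  cat("<twascore_pipeline>\n")
  cat("  risk genes:", length(x$risk_genes), "\n")
  cat("  cells scored:", nrow(x$panel), "\n")
  cat("  consensus signature:", paste(x$selection$consensus,
                                      collapse = ", "), "\n")
  cat("  best learner:", x$benchmark$best_learner,
      sprintf("(mean outer AUC %.3f)", max(x$benchmark$summary$mean_auc)),
      "\n")
  cat("  held-out test AUC:", sprintf("%.3f", x$test_eval$eval$auc), "\n")
  cat("  LOPO median AUC:", sprintf("%.3f", x$lopo$median_auc), "\n")
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
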