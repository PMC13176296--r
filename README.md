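# twascore

Per-cell activity scoring of TWAS risk genes, activity-state
stratification, consensus signature discovery, and patient-aware
validation — for single-cell RNA-seq cohorts, with a synthetic-data module
that makes every stage testable against planted ground truth.

## The problem

A transcriptome-wide association study (TWAS) tests each gene by combining
GWAS summary statistics ($z$ per SNP), eQTL-derived expression weights
($w$), and an LD reference ($V$):

$$ Z_{\text{gene}} = \frac{w^\top z}{\sqrt{w^\top V w}}, \qquad
   \text{risk genes: } q_{\text{BH}} < 0.05 . $$

Risk genes are population-level objects. `twascore` asks the cellular
question: which cells express the risk program, and can that state be
compressed into a small signature that generalizes across patients? The
package:

1. scores every cell for the risk set with five independent statistics
   (expression-matched module score, recovery-area/AUCell-type,
   rank-U/UCell-type, mean-normalized-rank/singscore-type, and a weighted
   Kolmogorov–Smirnov/ssGSEA-type score), normalizes each to [0, 1] and sums
   them into a composite score in [0, 5];
2. stratifies cells into low (≤ 25th percentile), median, and high (≥ 75th
   percentile) activity states and quantifies case/control enrichment by
   Ro/e (observed over chi-square-expected cell numbers);
3. derives a consensus signature as the exact intersection of seven feature
   selectors (LASSO, random forest, XGBoost, gradient boosting, a
   shadow-feature Boruta-type procedure, decision tree, and best-subset
   selection);
4. benchmarks classifiers with patient-grouped nested cross-validation
   (inner 5-fold tuning, outer 10-fold evaluation, best model by mean AUC)
   and validates the signature with leave-one-patient-out CV.

## Worked example

```r
library(twascore)

sim  <- simulate_dataset(sim_config(n_patients_case = 4,
                                    n_patients_control = 4,
                                    cells_per_patient = 60, n_genes = 400,
                                    n_risk_genes = 25,
                                    n_signature_genes = 4, seed = 1))
data <- sim$expression |>
  qc_filter(min_genes = 20) |>
  lognormalize()

panel  <- score_activity(data, sim$truth_risk_genes, seed = 1)
strata <- stratify_quartiles(panel)
strata
#> <activity_strata> cutpoints q25 = 1.1601 , q75 = 2.3722
#>
#>    low median   high
#>    120    240    120

roe_enrichment(strata, cell_info(data))
#> # A tibble: 6 × 5
#>   stratum group   observed expected   roe
#>   <chr>   <chr>      <int>    <dbl> <dbl>
#> 1 low     case          41       60 0.683
#> 2 median  case         124      120 1.03
#> 3 high    case          75       60 1.25
#> 4 low     control       79       60 1.32
#> 5 median  control      116      120 0.967
#> 6 high    control       45       60 0.75
```

High-activity cells are enriched in cases (Ro/e 1.25 > 1) and depleted in
controls (0.75 < 1), while low-activity cells show the mirror pattern — the
planted case/control difference in active-cell prevalence (35% vs 15%) read
back from the stratum-by-group table.

```r
task <- build_task(data, strata, sim$truth_risk_genes)
sel  <- consensus_select(task, seed = 1)
sel$consensus
#> [1] "g00274" "g00164" "g00368" "g00316" "g00400" "g00179" "g00173" "g00366"
#> [9] "g00323"
intersect(sel$consensus, sim$truth_signature_genes)
#> [1] "g00164" "g00179" "g00173"

lopo_cv(task, sel$consensus, seed = 1)
#> <lopo_report> median per-patient AUC = 0.9931 ( IQR 0.03955 ; 0 patient(s) excluded )
```

Three of the four planted signature genes sit in the consensus even in this
deliberately small cohort (at the package's default study size the tests
recover a median of 6/6 across seeds), and the selected signature separates
high from low cells in every held-out patient. `run_pipeline()`
chains all stages and writes every intermediate table plus a manifest;
`autoplot()` methods exist for panels, Ro/e tables, ROC results, TWAS scans
and reports, and `tidy()`/`glance()` for all result objects.

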