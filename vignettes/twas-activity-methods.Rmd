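---
title: "Scoring cells for TWAS risk-gene activity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cells for TWAS risk-gene activity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twascore)
```

## The question the package answers

A transcriptome-wide association study (TWAS) combines GWAS summary
statistics with eQTL-derived expression weights to nominate disease risk
genes. Those genes are defined at the population level; the follow-up
question is cellular: *which cells actually express the risk program?*
`twascore` answers it by scoring every cell of a single-cell RNA-seq
experiment for the composite activity of the risk-gene set, stratifying
cells into low/median/high activity states, quantifying how the high state
distributes across case and control donors, distilling a compact signature
of the high state by consensus feature selection, and validating that
signature with patient-aware cross-validation.

Everything is exercisable on synthetic data with planted ground truth, so
each stage's behaviour is testable without any external download.

## The TWAS stage

For a gene with cis-SNP weight vector $w$, GWAS z-scores $z$ and SNP
correlation (LD) matrix $V$, the gene-level association statistic is

$$ Z = \frac{w^\top z}{\sqrt{w^\top V w}}, $$

standard normal when the gene has no association. Genes whose predictive
variance $w^\top V w$ is numerically degenerate (tolerance $10^{-12}$) are
flagged untestable and excluded before multiple testing. P-values are
adjusted with the Benjamini–Hochberg step-up across all testable genes, and
the risk set is defined by the strict inequality $q < 0.05$ — a gene with
$q = 0.05$ exactly is *not* selected.

The synthetic fixture plants causal genes by shifting the mean of $z$ along
$Vw / \sqrt{w^\top V w}$, so the planted gene-level expectation equals the
requested shift; LD blocks are AR(1) with $\rho = 0.5$, which is positive
semi-definite in closed form.

## Quality control and normalization

QC keeps cells with 200–6000 detected genes (inclusive) and mitochondrial
fraction at most 15% (inclusive); the boundary cells survive because the
filter criteria are phrased as strict inequalities on the removal side.
Normalization is the standard library-size transform
$x \mapsto \ln(1 + 10^4\, x / \text{total})$, which preserves within-cell
ranks — the property the rank-based scores depend on. Highly variable genes
are ranked by the variance of log-normalized expression with a gene-id
tiebreak (a deliberately simple, deterministic criterion that is monotone in
dispersion on negative-binomial data); PCA standardizes genes, clips
z-values at ±10, and fixes each component's sign so its largest-magnitude
loading is positive, making embeddings reproducible across platforms.

## The five activity scores

Each cell receives five scores for the risk set $S$ ($n_s = |S|$, $G$ genes
measured). Ties in any within-cell ranking are broken by gene id, so all
scores are deterministic.

* **Module score** — mean expression of $S$ minus the mean of control genes
  sampled from average-expression-matched bins (24 bins, 100 controls per
  set gene, seeded). Controls are sampled from non-set genes of the bin,
  falling back to the whole bin when a bin holds no non-set gene.
* **Recovery-area score (AUCell-type)** — the area under the step curve of
  set genes recovered within the top $\lceil 0.05\,G \rceil$ ranks,
  normalized by the maximal achievable area, giving $[0,1]$.
* **Rank-U score (UCell-type)** — ranks clipped at `max_rank` (1500, or $G$
  when fewer genes are measured); with $U'$ the Mann–Whitney statistic of
  set ranks against the clipped complement, the score is
  $1 - U' / (n_s(\text{max\_rank} - n_s))$.
* **Mean normalized rank (singscore-type)** — mean of $(r - 0.5)/G$ over set
  genes (ascending ranks), centered by $-0.5$; zero means no enrichment.
* **Weighted KS score (ssGSEA-type)** — walking the descending ranking, the
  running sum gains $(G - i + 1)^{\alpha}$ (normalized over the set,
  $\alpha = 0.25$) at set genes and loses $1/(G - n_s)$ elsewhere; the score
  integrates the running sum over all positions.

Where the defaults are not dictated by the procedure itself (bins, controls,
top fraction, rank clip, $\alpha$) they follow the conventions of the
corresponding algorithm families.

Each column of the raw 5-score panel is z-scored and then min-max rescaled
to $[0,1]$. Because z-scoring is affine, the composition equals plain
min-max on any non-constant column; both steps are kept for fidelity to the
described procedure and the identity is asserted in the test suite. A
constant column maps to 0.5 so it is neutral in the sum. The composite
activity score is the row sum, in $[0, 5]$.

## Stratification and group enrichment

Cells at or below the 25th percentile of the composite score are the low
state, at or above the 75th the high state, the rest median. Percentiles use
linear interpolation between order statistics (R type 7), and the quartile
frame defaults to being computed within each cell type separately — the
analysis targets one cell population at a time — with an `"all"` scope
available. If every score is identical the procedure degenerates; all cells
are labelled median with a warning.

Group enrichment is the ratio of observed to expected cell numbers
(Ro/e) in the stratum-by-group table, with the chi-square expectation
$e_{sg} = n_{s\cdot} n_{\cdot g} / n$. Each group column satisfies the
conservation law $\sum_s e_{sg}\,\mathrm{Roe}_{sg} = n_{\cdot g}$, which the
tests assert.

## Consensus signature selection

The binary task uses only high (label 1) and low (label 0) cells — the
quartile construction makes the classes near-balanced by design — with the
log-normalized risk-gene expressions as features and the donor id retained
for grouping. Seven selectors are run:

| selector | implementation | cutoff |
|---|---|---|
| LASSO | `glmnet`, penalty by inner CV | non-zero coefficients |
| random forest | `ranger` impurity importance | top 10 |
| XGBoost | `xgboost`, depth 6, eta 0.3 | top 20 by gain |
| gradient boosting | `xgboost` configured classically (depth 2, eta 0.05, subsample 0.7) | top 20 by gain |
| Boruta-type | own shadow-feature procedure over `ranger` forests | confirmed, top 20 |
| decision tree | `rpart` impurity importance | top 20 |
| best-subset (ABESS-type) | own forward + splicing search | IC-chosen support |

The random-forest cutoff is top-$k$ rather than an absolute importance
threshold because absolute impurity importances do not transfer across
datasets; an absolute threshold remains available
(`params$rf_importance_min`). The LASSO keeps features by non-zero
coefficient of either sign, with a sign-restricted option
(`positive_only`), since restricting to positive coefficients discards
genes whose *low* expression marks the high state.

The Boruta-type procedure duplicates and permutes every feature, fits a
forest on real plus shadow features, counts a "hit" when a real feature's
importance exceeds the maximum shadow importance, and decides features by a
two-sided binomial test of the hit count against chance (p = 0.5) at
$\alpha = 0.01$ with Bonferroni correction across features. Rejected
features leave subsequent forests, and at least five shadow columns are
always kept so the max-shadow bar remains meaningful late in the run.
The forests use out-of-bag permutation importance rather than impurity
importance: impurity importance is computed in-sample, so a noise feature
that happens to be chance-correlated with the labels keeps a persistent
advantage over its freshly permuted shadows and can hover tentative
forever; out-of-bag importance gives such features no credit and restores
the intended null behaviour. Within the seven-selector consensus the
procedure runs with a lighter budget (30 iterations, 50-tree forests) than
the standalone default (100/100): decidable features resolve within about
twenty iterations at this correction level, and the consensus consumes only
the confirmed top-20.

Best-subset selection operates on the linear model of the 0/1 outcome: for
each support size $k$ the support is found by forward search refined by
splicing (swap) passes on the residual sum of squares — evaluated from the
Gram matrix, so the search cost is independent of the number of cells — and
$k$ is chosen by BIC, $n \log(\mathrm{RSS}/n) + k \log n$ (EBIC optional).
The linear-model surrogate keeps the search exact and fast; the test suite
pins it against exhaustive enumeration over all supports at small $p$.
A full splicing-style search over every support size is implemented rather
than the exhaustive variant even at small $p$, so the exhaustive oracle in
the tests stays independent of the implementation.

The consensus signature is the exact intersection of the seven lists,
ordered by mean rank across selectors. The intersection is monotone:
enlarging any one selector's list can only grow it.

## Patient-aware evaluation

All splitting is by whole patients, never by cells, because cells from one
donor are strongly dependent; a cell-level split leaks donor identity into
the test set. The 80/20 split assigns patients greedily in a seeded random
order, each to the side that keeps the realized train cell-fraction closest
to target (with few patients the achievable fraction is coarse; the realized
value is reported). The benchmark is nested cross-validation — patient-
grouped outer 10-fold for evaluation, inner 5-fold for hyperparameter
tuning — over a light learner panel (penalized logistic regression, naive
Bayes, k-NN, random forest, gradient boosting; each with at most three
values of one hyperparameter). The model with the highest mean outer AUC is
deemed best, ties resolved toward the simpler (earlier-listed) learner.

AUC is computed as the tie-aware probability that a random positive
outscores a random negative; ROC points come from the threshold sweep and PR
points are interpolation-free steps. Leave-one-patient-out validation fits a
logistic regression on the signature genes to all other donors' cells and
scores the held-out donor; donors whose cells are all one class are excluded
with the reason recorded, and the summary is the median and IQR of
per-donor AUCs.

## What the synthetic data emulates — and what it does not

The generator draws gene baseline means log-normal
($\mu_{\log} = \log 0.2$, $\sigma_{\log} = 1$), per-cell library-size
factors log-normal, and counts negative-binomial with a single dispersion
(0.5). Each donor contributes a fixed quota of "active" cells —
`round(active_fraction × cells_per_patient)`, so planted truth counts are
exact — in which risk genes are multiplied by $2^{1}$ and signature genes by
$2^{2}$. Defaults describe a cohort of 10 case and 10 control donors with
35% versus 15% active cells, a 125-gene risk set containing a 6-gene
signature. Risk genes are drawn from the expressed half of the baseline-mean
distribution, mirroring the fact that TWAS-testable genes carry expression
weights in a reference tissue and are therefore expressed genes; without
this, a planted fold-change on a never-detected gene would be vacuous.
Mitochondrial fraction is simulated as a covariate rather than as actual
mitochondrial counts, since the QC filter consumes only the fraction.

Problem sizes are chosen for desk-scale reproducibility: 200 cells per
donor and 2000 genes by default (the tests run the full pipeline at these
sizes across 20 seeds). The generator deliberately omits doublets, ambient
RNA, batch effects and cell-type hierarchies; passing tests therefore
demonstrate correctness of the procedures and recoverability of planted
signal under clean negative-binomial noise, not robustness to the full
mess of real single-cell data.

## Numerical and degenerate-case decisions

* Ranking ties: always broken by gene id (stable and platform-independent).
* Constant score columns normalize to 0.5; constant composite scores
  stratify to all-median with a warning.
* Untestable TWAS genes (predictive variance ≤ 1e-12) never enter BH.
* Zero-total cells make `lognormalize()` fail loudly — QC is expected to
  remove them first.
* Empty gene-set intersections, single-class AUC calls, sub-minimum patient
  counts and infeasible fold configurations are all hard errors, not silent
  degradations.
* Every stochastic step takes an explicit seed, and stage seeds are derived
  from the single pipeline seed; equal-seed pipeline runs produce
  byte-identical outputs.

## Known limitations

* The five scores are this package's implementations of the five published
  scoring ideas, verified against brute-force oracles of their defining
  formulas — they are not numerically identical to the upstream packages'
  outputs (different tie policies and normalizations).
* The best-subset selector optimizes the linear-model RSS, not the logistic
  likelihood; on near-separable tasks the supports usually coincide, but
  they are not guaranteed to.
* With very few donors the 80/20 patient split can be far from 80/20; the
  report carries the achieved fraction.
* Ro/e is a descriptive enrichment ratio; it comes with no significance
  statement.
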