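# A deterministic toy matrix used by several oracle checks: 5 cells x 8
# genes, values distinct within each cell.
toy_cells <- function() {
  set.seed(101)
  m <- matrix(sample(1:400, 40), 5, 8)
  colnames(m) <- sprintf("g%02d", 1:8)
  toy_lognorm(m)
}

test_that("module score is ~0 for the all-genes set and shifts linearly", {
  set.seed(5)
  m <- matrix(abs(rnorm(200 * 50, 2)), 200, 50)
  colnames(m) <- sprintf("g%02d", 1:50)
  d <- toy_lognorm(m)
  sc <- score_module_mean(d, colnames(m), seed = 3)
  expect_lt(max(abs(sc)), 0.2)

  # set = the highest-average genes, so adding a constant does not change
  # their expression bin and the same controls are drawn under the seed
  top <- names(sort(Matrix::colMeans(d$values), decreasing = TRUE))[1:5]
  base <- score_module_mean(d, top, n_bins = 5, seed = 3)
  d2 <- d
  m2 <- m
  m2[, top] <- m2[, top] + 1.5
  d2 <- toy_lognorm(m2)
  shifted <- score_module_mean(d2, top, n_bins = 5, seed = 3)
  expect_equal(shifted, base + 1.5, tolerance = 1e-10)
})

test_that("module score separates planted active cells", {
  s <- small_sim(seed = 4, cells_per_patient = 120)
  d <- lognormalize(small_qc(s$expression))
  sc <- score_module_mean(d, s$truth_risk_genes, seed = 4)
  active <- cell_info(d)$cell_id %in% s$truth_active_cells
  tt <- t.test(sc[active], sc[!active], alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("module score errors when no set gene is measured", {
  d <- toy_cells()
  expect_error(score_module_mean(d, c("nope1", "nope2")), "nope1")
})

test_that("AUCell-type score hits its extremes and matches the oracle", {
  # 6 genes; expression ranks fully determined
  m <- matrix(c(60, 50, 40, 30, 20, 10), 1, 6,
              dimnames = list("c1", paste0("g", 1:6)))
  d <- toy_lognorm(m)
  # set occupies the top ranks -> maximal score
  expect_equal(unname(score_aucell(d, c("g1", "g2"), top_fraction = 0.5)), 1)
  # no set gene inside the top window -> 0
  expect_equal(unname(score_aucell(d, c("g5", "g6"), top_fraction = 0.5)), 0)
  # brute-force oracle on the stated 6-gene configuration
  expect_equal(unname(score_aucell(d, c("g1", "g3"), top_fraction = 0.5)),
               aucell_oracle(m[1, ], colnames(m), c("g1", "g3"), top = 3))
  expect_error(score_aucell(d, "g1", top_fraction = 0), "top rank")
})

test_that("AUCell-type score equals the oracle on random cells", {
  d <- toy_cells()
  m <- as.matrix(d$values)
  for (i in 1:5) {
    sets <- list(c("g01", "g03"), c("g02", "g05", "g08"), "g07")
    for (set in sets) {
      expect_equal(
        unname(score_aucell(d, set, top_fraction = 0.5))[i],
        aucell_oracle(m[i, ], colnames(m), set, top = 4))
    }
  }
})

test_that("UCell-type score spans [0, 1] and matches pairwise counting", {
  m <- matrix(c(60, 50, 40, 30, 20, 10), 1, 6,
              dimnames = list("c1", paste0("g", 1:6)))
  d <- toy_lognorm(m)
  expect_equal(unname(score_ucell(d, "g1", max_rank = 5)), 1)
  expect_equal(unname(score_ucell(d, "g6", max_rank = 5)), 0)
  expect_error(score_ucell(d, paste0("g", 1:5), max_rank = 5), "max_rank")

  set.seed(33)
  x <- sample(1:1000, 50)
  names(x) <- sprintf("g%02d", 1:50)
  d2 <- toy_lognorm(matrix(x, 1, dimnames = list("c1", names(x))))
  set <- c("g03", "g11", "g27", "g40", "g49")
  expect_equal(unname(score_ucell(d2, set, max_rank = 50)),
               ucell_oracle(x, names(x), set, max_rank = 50))
  # and the brute-force U statistic itself agrees with pairwise comparisons
  r <- rank_desc_oracle(x, names(x))
  # U' = number of (set, complement) pairs where the complement gene
  # outranks the set gene
  u_pair <- sum(outer(r[set], r[setdiff(names(x), set)], ">"))
  u_formula <- sum(r[set]) - length(set) * (length(set) + 1) / 2
  expect_equal(u_formula, u_pair)
})

test_that("singscore-type score matches hand arithmetic and is rank-based", {
  m <- matrix(seq(100, 10, by = -10), 1, 10,
              dimnames = list("c1", sprintf("g%02d", 1:10)))
  d <- toy_lognorm(m)
  # set holds the top 2 ranks of 10 genes: (9.5 + 8.5)/2/10 - 0.5 = 0.40
  expect_equal(unname(score_singscore(d, c("g01", "g02"))), 0.40)
  expect_equal(unname(score_singscore(d, colnames(m))), 0)
  expect_equal(unname(score_singscore(d, c("g03", "g07"))),
               singscore_oracle(m[1, ], colnames(m), c("g03", "g07")))
  # invariant under strictly monotone transforms
  d2 <- toy_lognorm(exp(m / 40))
  expect_equal(score_singscore(d2, c("g03", "g07")),
               score_singscore(d, c("g03", "g07")))
})

test_that("ssGSEA-type score equals the enumerated running sum", {
  m <- matrix(c(80, 10, 70, 30, 60, 20, 50, 40), 1, 8,
              dimnames = list("c1", sprintf("g%d", 1:8)))
  d <- toy_lognorm(m)
  set <- c("g1", "g4", "g7")
  # unweighted (alpha = 0) integrated KS running sum
  expect_equal(unname(score_ssgsea(d, set, alpha = 0)),
               ssgsea_oracle(m[1, ], colnames(m), set, alpha = 0))
  # default weighting
  expect_equal(unname(score_ssgsea(d, set, alpha = 0.25)),
               ssgsea_oracle(m[1, ], colnames(m), set, alpha = 0.25))
  # set at the very bottom of the ranking scores negative
  expect_lt(unname(score_ssgsea(d, c("g2", "g6"), alpha = 0.25)), 0)
  # identical rankings give identical scores
  d2 <- toy_lognorm(rbind(c1 = m[1, ], c2 = 2 * m[1, ]))
  sc <- score_ssgsea(d2, set)
  expect_equal(unname(sc[1]), unname(sc[2]))
  expect_error(score_ssgsea(d, colnames(m)), "complement")
})

test_that("all five scores ignore gene-column ordering", {
  d <- toy_cells()
  m <- as.matrix(d$values)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  dp <- toy_lognorm(m[, perm])
  set <- c("g02", "g05", "g07")
  expect_equal(score_module_mean(dp, set, n_bins = 4, seed = 2),
               score_module_mean(d, set, n_bins = 4, seed = 2))
  expect_equal(score_aucell(dp, set, 0.5), score_aucell(d, set, 0.5))
  expect_equal(score_ucell(dp, set, 7), score_ucell(d, set, 7))
  expect_equal(score_singscore(dp, set), score_singscore(d, set))
  expect_equal(score_ssgsea(dp, set), score_ssgsea(d, set))
})

test_that("rank-based scores are invariant under monotone transforms", {
  d <- toy_cells()
  m <- as.matrix(d$values)
  dt <- toy_lognorm(sqrt(m) + 2)
  set <- c("g01", "g06")
  expect_equal(score_aucell(dt, set, 0.4), score_aucell(d, set, 0.4))
  expect_equal(score_ucell(dt, set, 7), score_ucell(d, set, 7))
  expect_equal(score_singscore(dt, set), score_singscore(d, set))
})

test_that("panel normalization is min-max after an inert z-score", {
  set.seed(77)
  raw <- cbind(a = rnorm(40), b = runif(40, 5, 9), c = rep(2, 40))
  norm <- normalize_panel(raw)
  expect_equal(unname(apply(norm[, c("a", "b")], 2, min)), c(0, 0))
  expect_equal(unname(apply(norm[, c("a", "b")], 2, max)), c(1, 1))
  expect_true(all(norm[, "c"] == 0.5))
  # z-scoring is affine, so minmax(zscore(x)) = minmax(x)
  plain_minmax <- apply(raw[, c("a", "b")], 2, function(x)
    (x - min(x)) / (max(x) - min(x)))
  expect_equal(norm[, c("a", "b")], plain_minmax, tolerance = 1e-12)
  expect_error(normalize_panel(raw[1, , drop = FALSE]), "2 cells")
})

test_that("composite score sums normalized rows onto [0, 5]", {
  expect_equal(unname(composite_score(matrix(1, 1, 5))), 5)
  expect_equal(unname(composite_score(matrix(0, 1, 5))), 0)
  expect_equal(unname(composite_score(
    matrix(c(0.2, 0.4, 0.6, 0.8, 1.0), 1))), 3.0)
  expect_error(composite_score(matrix(1.5, 1, 5)), "0, 1")
})

test_that("score correlations behave at the extremes", {
  x <- seq_len(20)
  cc <- score_correlation(cbind(a = x, b = rev(x)))
  expect_equal(diag(cc), c(a = 1, b = 1))
  expect_equal(cc["a", "b"], -1)
  cc2 <- score_correlation(cbind(a = x, b = rep(1, 20)))
  expect_true(is.na(cc2["a", "b"]))
})

test_that("score_activity keeps rows aligned and bounded", {
  s <- small_sim(seed = 9)
  d <- lognormalize(small_qc(s$expression))
  p <- score_activity(d, s$truth_risk_genes, max_rank = 300, seed = 9)
  expect_identical(p$cell_id, cell_info(d)$cell_id)
  expect_true(all(p$scoring >= 0 & p$scoring <= 5))
  norm_cols <- as.matrix(p[, paste0("norm_",
    c("module_mean", "aucell", "ucell", "singscore", "ssgsea"))])
  expect_equal(unname(p$scoring), unname(rowSums(norm_cols)))
  # five raw scores positively correlated on planted data
  cc <- score_correlation(as.matrix(
    p[, c("module_mean", "aucell", "ucell", "singscore", "ssgsea")]))
  expect_true(all(cc[upper.tri(cc)] > 0))
})

test_that("composite score of active cells grows with the planted effect", {
  gaps <- vapply(c(0.5, 1, 2), function(fc) {
    s <- small_sim(seed = 6, effect_log2fc = fc, signature_log2fc = fc + 1)
    d <- lognormalize(small_qc(s$expression))
    p <- score_activity(d, s$truth_risk_genes, max_rank = 300, seed = 6)
    active <- cell_info(d)$cell_id %in% s$truth_active_cells
    mean(p$scoring[active]) - mean(p$scoring[!active])
  }, numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) > 0))
})
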