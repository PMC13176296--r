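# A small synthetic task with one perfectly separating feature plus noise.
separator_task <- function(seed, n = 80, p_noise = 10) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(sep = y * 2 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, sprintf("noise%02d",
                                                  seq_len(p_noise)))))
  structure(
    list(features = x, outcome = y,
         patient = rep(sprintf("p%d", 1:4), length.out = n),
         cell_id = sprintf("c%03d", seq_len(n)),
         feature_names = colnames(x), missing_genes = character(0)),
    class = "classif_task")
}

# Label-independent features.
null_task <- function(seed, n = 100, p = 10) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  structure(
    list(features = x, outcome = rep(0:1, length.out = n),
         patient = rep(sprintf("p%d", 1:4), length.out = n),
         cell_id = sprintf("c%03d", 1:n),
         feature_names = colnames(x), missing_genes = character(0)),
    class = "classif_task")
}

test_that("build_task drops median cells and encodes high as 1", {
  set.seed(55)
  m <- matrix(abs(rnorm(400 * 12, 3)), 400, 12)
  colnames(m) <- sprintf("g%02d", 1:12)
  d <- toy_lognorm(m, patient = rep(sprintf("p%d", 1:4), each = 100))
  labels <- structure(list(labels = tibble::tibble(
    cell_id = cell_info(d)$cell_id,
    stratum = factor(rep(c("low", "median", "high"), c(100, 200, 100)),
                     levels = c("low", "median", "high")))),
    class = "activity_strata")
  task <- build_task(d, labels, sprintf("g%02d", 1:6))
  expect_identical(length(task$outcome), 200L)
  expect_identical(sum(task$outcome == 1), 100L)
  high_cells <- labels$labels$cell_id[labels$labels$stratum == "high"]
  expect_true(all(task$outcome[task$cell_id %in% high_cells] == 1))
  expect_identical(task$feature_names, sprintf("g%02d", 1:6))
})

test_that("build_task reports risk genes missing from the matrix", {
  st <- small_task(seed = 2)
  expect_message(
    task <- build_task(st$data, st$strata,
                       c(st$sim$truth_risk_genes, "ghost1")),
    "ghost1")
  expect_identical(task$missing_genes, "ghost1")
  expect_false("ghost1" %in% task$feature_names)
})

test_that("a perfectly separating feature tops every selector", {
  hits <- sapply(1:20, function(sd) {
    task <- separator_task(seed = sd)
    vapply(c("lasso", "rf", "xgb", "gbm", "boruta", "dtree", "abess"),
           function(m) {
             f <- select_features(task, m, params = list(
               max_iter = 20, num_trees = 50, nfolds = 3), seed = sd)
             nrow(f) >= 1 && f$feature[1] == "sep"
           }, logical(1))
  })
  # per-method majority over the 20 seeds
  expect_true(all(rowMeans(hits) > 0.5))
})

test_that("lasso at the cross-validated penalty prunes null features", {
  sizes <- vapply(1:20, function(sd) {
    nrow(select_features(null_task(seed = sd), "lasso",
                         params = list(nfolds = 3), seed = sd))
  }, numeric(1))
  expect_lte(median(sizes), 2)
})

test_that("selectors are deterministic under a fixed seed", {
  task <- separator_task(seed = 3)
  for (m in c("lasso", "rf", "xgb", "gbm", "boruta", "dtree", "abess")) {
    a <- select_features(task, m, params = list(max_iter = 10,
                                                num_trees = 50), seed = 7)
    b <- select_features(task, m, params = list(max_iter = 10,
                                                num_trees = 50), seed = 7)
    expect_identical(a, b)
  }
  expect_error(select_features(task, "svm"), "unknown selection method")
})

test_that("boruta separates signal from noise and rejects constants", {
  task <- separator_task(seed = 5, n = 120, p_noise = 6)
  task$features <- cbind(task$features, const = rep(1, 120))
  task$feature_names <- colnames(task$features)
  b <- boruta_select(task, max_iter = 30, seed = 5, num_trees = 50)
  expect_identical(b$decision[b$feature == "sep"], "confirmed")
  expect_identical(b$decision[b$feature == "const"], "rejected")
  expect_identical(b$hits[b$feature == "const"], 0L)
  expect_error(boruta_select(task, max_iter = 3), "max_iter")
})

test_that("boruta rejects pure-noise features in nearly all runs", {
  # n is large enough that chance in-sample correlation cannot make a
  # noise feature genuinely predictive
  rejected <- vapply(1:20, function(sd) {
    task <- null_task(seed = sd, n = 400, p = 4)
    b <- boruta_select(task, max_iter = 100, seed = sd, num_trees = 40)
    mean(b$decision == "rejected")
  }, numeric(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("best-subset search matches exhaustive enumeration on small p", {
  for (sd in 1:5) {
    set.seed(sd)
    n <- 60; p <- 8
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL,
                                                 sprintf("f%d", 1:p)))
    y_prob <- stats::plogis(2 * x[, 2] - 1.5 * x[, 5])
    y <- as.integer(runif(n) < y_prob)
    if (length(unique(y)) < 2) next
    task <- structure(
      list(features = x, outcome = y,
           patient = rep("p1", n), cell_id = as.character(1:n),
           feature_names = colnames(x), missing_genes = character(0)),
      class = "classif_task")
    got <- abess_select(task, k_max = 4)

    # exhaustive oracle: all supports of size <= 4, BIC-chosen
    rss_ex <- function(supp) {
      fit <- stats::lm(y ~ ., data = data.frame(y = y,
                                                x[, supp, drop = FALSE]))
      sum(stats::residuals(fit)^2)
    }
    best <- list(ic = Inf, supp = character(0))
    for (k in 0:4) {
      combs <- utils::combn(colnames(x), k, simplify = FALSE)
      if (k == 0) combs <- list(character(0))
      for (supp in combs) {
        rss <- if (k == 0) sum((y - mean(y))^2) else rss_ex(supp)
        ic <- n * log(rss / n) + k * log(n)
        if (ic < best$ic) best <- list(ic = ic, supp = supp)
      }
    }
    expect_setequal(got$support, best$supp)
  }
})

test_that("consensus intersection is exact, ordered, and monotone", {
  base <- tibble::tibble(feature = c("a", "b", "c"),
                         importance = c(3, 2, 1), rank = 1:3)
  seven <- setNames(rep(list(base), 7),
                    c("lasso", "rf", "xgb", "gbm", "boruta", "dtree",
                      "abess"))
  expect_identical(consensus_intersection(seven), c("a", "b", "c"))

  disjoint <- seven
  disjoint$rf <- tibble::tibble(feature = c("x", "y"),
                                importance = c(2, 1), rank = 1:2)
  expect_identical(consensus_intersection(disjoint), character(0))

  # enlarging one selector's list never shrinks the intersection
  shrunk <- seven
  shrunk$xgb <- base[1:2, ]
  small_cons <- consensus_intersection(shrunk)
  grown <- shrunk
  grown$xgb <- base
  expect_true(all(small_cons %in% consensus_intersection(grown)))

  expect_error(consensus_intersection(seven[-2]), "rf")
})

test_that("consensus ordering follows mean rank across selectors", {
  seven <- setNames(rep(list(tibble::tibble(
    feature = c("a", "b"), importance = c(2, 1), rank = 1:2)), 7),
    c("lasso", "rf", "xgb", "gbm", "boruta", "dtree", "abess"))
  # flip the ranking in four of seven selectors -> 'b' wins on mean rank
  for (m in c("lasso", "rf", "xgb", "gbm")) {
    seven[[m]] <- tibble::tibble(feature = c("b", "a"),
                                 importance = c(2, 1), rank = 1:2)
  }
  expect_identical(consensus_intersection(seven), c("b", "a"))
})
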