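make_task <- function(x, y, patient) {
  structure(
    list(features = x, outcome = y, patient = patient,
         cell_id = sprintf("c%04d", seq_along(y)),
         feature_names = colnames(x), missing_genes = character(0)),
    class = "classif_task")
}

test_that("compute_auc matches enumeration on known cases", {
  expect_equal(compute_auc(c(1, 2, 3, 10, 11, 12),
                           c(0, 0, 0, 1, 1, 1))$auc, 1)
  got <- compute_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(got$auc, 0.75)
  expect_equal(got$auc, auc_oracle(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("compute_auc equals the pairwise oracle on every small instance", {
  score_pool <- c(0.1, 0.2, 0.2, 0.5, 0.7, 0.7)
  set.seed(44)
  for (n in 2:6) {
    labs <- expand.grid(rep(list(0:1), n))
    for (i in seq_len(nrow(labs))) {
      y <- as.integer(labs[i, ])
      if (length(unique(y)) < 2) next
      for (rep in 1:3) {
        s <- sample(score_pool, n, replace = TRUE)
        expect_equal(compute_auc(s, y)$auc, auc_oracle(s, y))
      }
    }
  }
})

test_that("ROC and PR points trace the threshold sweep", {
  got <- compute_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(got$roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(got$roc$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_equal(got$pr$recall, c(0.5, 0.5, 1, 1))
  expect_equal(got$pr$precision, c(1, 0.5, 2 / 3, 0.5))
  # cross-check the AUC against an independent implementation
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- runif(50); y <- rbinom(50, 1, 0.5)
  if (length(unique(y)) == 2) {
    expect_equal(compute_auc(s, y)$auc,
                 as.numeric(suppressMessages(
                   pROC::auc(y, s, direction = "<", levels = c(0, 1)))))
  }
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(10)
  s <- runif(10000)
  y <- rep(0:1, 5000)
  expect_equal(compute_auc(s, y)$auc, 0.5, tolerance = 0.02)
})

test_that("patient-grouped split hits the target and never splits patients", {
  set.seed(1)
  x <- matrix(rnorm(1000 * 3), 1000, dimnames = list(NULL, c("a", "b", "c")))
  task <- make_task(x, rep(0:1, 500), rep(sprintf("p%02d", 1:10), each = 100))
  sp <- patient_grouped_split(task, 0.8, seed = 2)
  expect_identical(length(sp$train$outcome), 800L)
  expect_identical(sum(sp$assignment$side == "train"), 8L)
  expect_length(intersect(unique(sp$train$patient),
                          unique(sp$test$patient)), 0)
  expect_length(intersect(sp$train$cell_id, sp$test$cell_id), 0)
  expect_setequal(c(sp$train$cell_id, sp$test$cell_id), task$cell_id)
  expect_equal(sp$achieved_fraction, 0.8)
})

test_that("two patients always land on opposite sides", {
  x <- matrix(rnorm(40), 20, dimnames = list(NULL, c("a", "b")))
  task <- make_task(x, rep(0:1, 10), rep(c("pA", "pB"), each = 10))
  for (sd in 1:5) {
    sp <- patient_grouped_split(task, 0.9, seed = sd)
    expect_identical(sort(sp$assignment$side), c("test", "train"))
  }
  one <- make_task(x, rep(0:1, 10), rep("pA", 20))
  expect_error(patient_grouped_split(one), "2 patients")
})

test_that("nested CV reports one AUC per outer fold and picks the best", {
  st <- small_task(seed = 8, n_patients_case = 5, n_patients_control = 5,
                   cells_per_patient = 60)
  lrn <- default_learners()[c("logistic", "naive_bayes")]
  bm <- nested_cv_benchmark(st$task, learners = lrn, inner_folds = 3,
                            outer_folds = 5, seed = 4)
  expect_identical(nrow(bm$fold_aucs), 10L)  # 2 learners x 5 folds
  expect_identical(sum(bm$fold_aucs$learner == "logistic"), 5L)
  expect_true(all(bm$fold_aucs$auc >= 0 & bm$fold_aucs$auc <= 1,
                  na.rm = TRUE))
  expect_identical(bm$best_learner,
                   bm$summary$learner[which.max(bm$summary$mean_auc)])

  solo <- nested_cv_benchmark(st$task, learners = lrn["logistic"],
                              inner_folds = 3, outer_folds = 5, seed = 4)
  expect_identical(solo$best_learner, "logistic")
})

test_that("fold construction fails loudly when patients are too few", {
  x <- matrix(rnorm(60), 30, dimnames = list(NULL, c("a", "b")))
  task <- make_task(x, rep(0:1, 15), rep(c("pA", "pB", "pC"), each = 10))
  expect_error(nested_cv_benchmark(task, outer_folds = 10, seed = 1),
               "infeasible")
})

test_that("model evaluation never reads the test set during fitting", {
  st <- small_task(seed = 12)
  sp <- patient_grouped_split(st$task, 0.8, seed = 1)
  lrn <- default_learners()$logistic
  ev1 <- evaluate_model(sp$train, sp$test, lrn, seed = 2)
  # canary: corrupt the test features entirely
  poisoned <- sp$test
  poisoned$features[] <- poisoned$features +
    matrix(rnorm(length(poisoned$features), sd = 5),
           nrow(poisoned$features))
  ev2 <- evaluate_model(sp$train, poisoned, lrn, seed = 2)
  expect_identical(coef(ev1$model), coef(ev2$model))
  expect_identical(lrn$predict(ev1$model, sp$train$features),
                   lrn$predict(ev2$model, sp$train$features))
})

test_that("LOPO-CV scores every eligible patient and excludes single-class", {
  st <- small_task(seed = 14)
  sig <- st$sim$truth_signature_genes
  lp <- lopo_cv(st$task, sig, seed = 3)
  expect_identical(nrow(lp$per_patient), 6L)
  expect_true(all(!lp$per_patient$excluded))
  expect_true(all(lp$per_patient$auc >= 0 & lp$per_patient$auc <= 1))

  # force one patient to be all-high: it must be excluded with a reason
  task2 <- st$task
  task2$outcome[task2$patient == "case01"] <- 1L
  lp2 <- lopo_cv(task2, sig, seed = 3)
  row <- lp2$per_patient[lp2$per_patient$patient == "case01", ]
  expect_true(row$excluded)
  expect_identical(row$reason, "single class")
  expect_identical(sum(!lp2$per_patient$excluded), 5L)
})

test_that("LOPO-CV requires features from the task and enough patients", {
  st <- small_task(seed = 14)
  expect_error(lopo_cv(st$task, c("not_a_gene")), "task features")
  x <- matrix(rnorm(60), 30, dimnames = list(NULL, c("a", "b")))
  two <- make_task(x, rep(0:1, 15), rep(c("pA", "pB"), each = 15))
  expect_error(lopo_cv(two, "a"), "3 patients")
})
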