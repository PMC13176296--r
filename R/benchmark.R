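#' AUC with ROC and precision-recall points
#'
#' The AUC is the probability that a random positive outscores a random
#' negative, with ties counting one half (equivalently the normalized
#' Mann-Whitney U computed from average ranks). ROC points come from a
#' threshold sweep over the distinct scores; PR points are the
#' interpolation-free step points of precision against recall.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or two-level factor).
#' @return A list of class `roc_result`: `auc`, `roc` (tibble `threshold`,
#'   `fpr`, `tpr`), `pr` (tibble `threshold`, `recall`, `precision`).
#' @export
compute_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length",
                                        call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  last <- !duplicated(ss, fromLast = TRUE)  # one point per distinct score
  tp <- cumsum(ys)[last]; fp <- cumsum(1 - ys)[last]
  roc <- tibble::tibble(
    threshold = c(Inf, ss[last]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
  pr <- tibble::tibble(
    threshold = ss[last],
    recall = tp / n1,
    precision = tp / (tp + fp)
  )
  structure(list(auc = auc, roc = roc, pr = pr), class = "roc_result")
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary",
                                      call. = FALSE)
  as.integer(labels)
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", signif(x$auc, 4), "(", nrow(x$roc) - 1,
      "distinct thresholds )\n")
  invisible(x)
}

#' ROC curve plot
#'
#' @param object A [compute_auc()] result.
#' @param ... Unused.
#' @return A ggplot ROC curve annotated with the AUC.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Patient-grouped train/test split
#'
#' Whole patients are assigned to one side only (no cell of a patient may
#' appear on both sides). Patients are visited in a seeded random order and
#' each is assigned greedily to the side that keeps the realized train
#' cell-fraction closest to `train_fraction`; both sides always receive at
#' least one patient.
#'
#' @param task A [build_task()] result with >= 2 patients.
#' @param train_fraction Target fraction of cells in the training set.
#' @param seed Integer seed.
#' @return A list of class `patient_split`: `train` and `test` tasks,
#'   `assignment` tibble (patient, side, n_cells), `achieved_fraction`.
#' @export
patient_grouped_split <- function(task, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(task, "classif_task"))
  patients <- unique(task$patient)
  if (length(patients) < 2) stop("need at least 2 patients to split",
                                 call. = FALSE)
  set.seed(as.integer(seed))
  ord <- sample(patients)
  n_cells <- table(task$patient)[ord]
  total <- length(task$outcome)
  target <- train_fraction * total
  train_cells <- 0
  side <- setNames(character(length(ord)), ord)
  for (p in ord) {
    if (abs(train_cells + n_cells[[p]] - target) <=
        abs(train_cells - target)) {
      side[p] <- "train"
      train_cells <- train_cells + n_cells[[p]]
    } else {
      side[p] <- "test"
    }
  }
  if (all(side == "train")) side[ord[length(ord)]] <- "test"
  if (all(side == "test")) side[ord[1]] <- "train"
  train_idx <- which(task$patient %in% names(side)[side == "train"])
  test_idx <- which(task$patient %in% names(side)[side == "test"])
  assignment <- tibble::tibble(patient = names(side),
                               side = unname(side),
                               n_cells = as.integer(n_cells))
  structure(
    list(
      train = task_subset(task, train_idx),
      test = task_subset(task, test_idx),
      assignment = assignment,
      achieved_fraction = length(train_idx) / total
    ),
    class = "patient_split"
  )
}

#' Default learner panel for the benchmark
#'
#' Five light, representative binary classifiers, ordered simple-first (the
#' order is the deterministic tiebreak when mean AUCs tie): penalized
#' logistic regression, naive Bayes, k-nearest neighbours, random forest and
#' gradient boosting. Each carries a tiny tuning grid (at most 3 values of
#' one hyperparameter) for the inner CV.
#'
#' @return Named list of learner specifications (`name`, `grid`, `fit`,
#'   `predict`).
#' @export
default_learners <- function() {
  list(
    logistic = list(
      name = "logistic", grid = list(lambda = c(0.001, 0.01, 0.1)),
      fit = function(x, y, hp, seed) {
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = hp$lambda)
      },
      predict = function(model, x) {
        as.numeric(predict(model, newx = x, type = "response"))
      }
    ),
    naive_bayes = list(
      name = "naive_bayes", grid = list(laplace = 0),
      fit = function(x, y, hp, seed) {
        e1071::naiveBayes(x, factor(y, levels = 0:1), laplace = hp$laplace)
      },
      predict = function(model, x) {
        unname(predict(model, x, type = "raw")[, "1"])
      }
    ),
    knn = list(
      name = "knn", grid = list(k = c(5, 15, 31)),
      fit = function(x, y, hp, seed) list(x = x, y = y, k = hp$k),
      predict = function(model, x) {
        pr <- class::knn(model$x, x, factor(model$y, levels = 0:1),
                         k = model$k, prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == "1", p_win, 1 - p_win)
      }
    ),
    random_forest = list(
      name = "random_forest", grid = list(mtry_frac = c(0.1, 0.33)),
      fit = function(x, y, hp, seed) {
        ranger::ranger(x = x, y = factor(y, levels = 0:1), num.trees = 200,
                       mtry = max(1, floor(hp$mtry_frac * ncol(x))),
                       probability = TRUE, seed = seed, num.threads = 1)
      },
      predict = function(model, x) {
        predict(model, data = x, num.threads = 1)$predictions[, "1"]
      }
    ),
    gboost = list(
      name = "gboost", grid = list(nrounds = c(50, 150)),
      fit = function(x, y, hp, seed) {
        xgb_fit(x, y, nrounds = hp$nrounds, eta = 0.1, max_depth = 3,
                seed = seed)
      },
      predict = function(model, x) {
        as.numeric(predict(model, xgboost::xgb.DMatrix(x, nthread = 1)))
      }
    )
  )
}

# Round-robin patient-grouped fold assignment over a seeded shuffle.
patient_folds <- function(patients, n_folds, seed) {
  uniq <- unique(patients)
  if (length(uniq) < n_folds) {
    stop("fold assignment infeasible: ", length(uniq), " patients for ",
         n_folds, " folds", call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold_of <- setNames(rep_len(seq_len(n_folds), length(uniq)), sample(uniq))
  unname(fold_of[patients])
}

expand_grid_list <- function(grid) {
  g <- do.call(expand.grid, c(grid, list(KEEP.OUT.ATTRS = FALSE,
                                         stringsAsFactors = FALSE)))
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# Inner patient-grouped CV: mean AUC per grid point, best hyperparameters.
tune_learner <- function(learner, task, inner_folds, seed) {
  grid_pts <- expand_grid_list(learner$grid)
  if (length(grid_pts) == 1) return(grid_pts[[1]])
  folds <- patient_folds(task$patient, inner_folds, seed)
  mean_auc <- vapply(grid_pts, function(hp) {
    aucs <- vapply(seq_len(max(folds)), function(f) {
      tr <- task_subset(task, which(folds != f))
      va <- task_subset(task, which(folds == f))
      if (length(unique(va$outcome)) < 2 ||
          length(unique(tr$outcome)) < 2) return(NA_real_)
      model <- learner$fit(tr$features, tr$outcome, hp, seed)
      compute_auc(learner$predict(model, va$features), va$outcome)$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  grid_pts[[which.max(mean_auc)]]
}

#' Nested cross-validated learner benchmark
#'
#' Outer folds are patient-grouped; within each outer-training set an inner
#' patient-grouped CV tunes every learner's (tiny) hyperparameter grid; the
#' tuned learner is refitted on the whole outer-training set and scored on
#' the held-out fold. The learner with the highest mean outer AUC is deemed
#' best, with ties broken toward the simpler (earlier-listed) learner.
#'
#' @param task A [build_task()] result (typically the training side of
#'   [patient_grouped_split()]).
#' @param learners Learner panel, e.g. [default_learners()].
#' @param inner_folds,outer_folds Fold counts of the nested scheme.
#' @param seed Integer seed.
#' @return A list of class `eval_report`: `fold_aucs` tibble (learner, fold,
#'   auc), `summary` tibble (learner, mean_auc), `best_learner`,
#'   `best_params` per learner.
#' @export
nested_cv_benchmark <- function(task, learners = default_learners(),
                                inner_folds = 5, outer_folds = 10,
                                seed = 1L) {
  stopifnot(inherits(task, "classif_task"), length(learners) >= 1)
  folds <- patient_folds(task$patient, outer_folds, seed)
  rows <- list()
  best_params <- list()
  for (li in seq_along(learners)) {
    lrn <- learners[[li]]
    for (f in seq_len(outer_folds)) {
      tr <- task_subset(task, which(folds != f))
      te <- task_subset(task, which(folds == f))
      if (length(unique(tr$outcome)) < 2) {
        stop("outer fold ", f, " leaves a single-class training set; ",
             "reduce outer_folds or rebalance patients", call. = FALSE)
      }
      hp <- tune_learner(lrn, tr, inner_folds, seed + f)
      model <- lrn$fit(tr$features, tr$outcome, hp, seed + f)
      auc <- if (length(unique(te$outcome)) < 2) NA_real_ else
        compute_auc(lrn$predict(model, te$features), te$outcome)$auc
      rows[[length(rows) + 1]] <- tibble::tibble(
        learner = lrn$name, fold = f, auc = auc)
      best_params[[lrn$name]] <- hp
    }
  }
  fold_aucs <- dplyr::bind_rows(rows)
  summary <- fold_aucs |>
    dplyr::group_by(.data$learner) |>
    dplyr::summarise(mean_auc = mean(.data$auc, na.rm = TRUE),
                     .groups = "drop")
  # preserve panel order for the simple-first tiebreak
  summary <- summary[match(vapply(learners, `[[`, "", "name"),
                           summary$learner), ]
  best <- summary$learner[which.max(summary$mean_auc)]
  structure(
    list(fold_aucs = fold_aucs, summary = summary, best_learner = best,
         best_params = best_params, outer_folds = outer_folds,
         seed = as.integer(seed)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> mean outer AUC by learner:\n")
  print(as.data.frame(x$summary))
  cat("best learner:", x$best_learner, "\n")
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$fold_aucs

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    best_learner = x$best_learner,
    best_mean_auc = x$summary$mean_auc[x$summary$learner == x$best_learner],
    outer_folds = x$outer_folds
  )
}

#' Box plot of outer-fold AUCs per learner
#'
#' @param object A [nested_cv_benchmark()] report.
#' @param ... Unused.
#' @return A ggplot of fold AUC distributions.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$fold_aucs,
                  ggplot2::aes(x = .data$learner, y = .data$auc)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "outer-fold AUC") +
    ggplot2::theme_minimal()
}

#' Fit a tuned learner on a training task and score a test task
#'
#' Model fitting uses the training cells only; the test task contributes
#' nothing to the fit.
#'
#' @param train,test [build_task()]-shaped tasks.
#' @param learner A learner spec (one element of [default_learners()]).
#' @param hp Hyperparameter list (one grid point); defaults to the first.
#' @param seed Integer seed.
#' @return A list: `model`, `scores` (test predictions), `eval` (a
#'   [compute_auc()] result on the test set).
#' @export
evaluate_model <- function(train, test, learner, hp = NULL, seed = 1L) {
  if (is.null(hp)) hp <- expand_grid_list(learner$grid)[[1]]
  model <- learner$fit(train$features, train$outcome, hp, seed)
  scores <- learner$predict(model, test$features)
  list(model = model, scores = scores,
       eval = compute_auc(scores, test$outcome))
}

#' Leave-one-patient-out validation of a signature
#'
#' Each patient is held out exactly once; a logistic regression on the
#' signature genes is trained on all other patients' cells and the held-out
#' patient's cells are scored. Patients whose cells are all one class are
#' excluded with reason `"single class"`.
#'
#' @param task A [build_task()] result with >= 3 patients.
#' @param signature Character vector of signature genes (must be task
#'   features).
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @return A list of class `lopo_report`: `per_patient` tibble (patient,
#'   n_cells, auc, excluded, reason), `median_auc`, `iqr_auc`.
#' @export
lopo_cv <- function(task, signature, seed = 1L) {
  stopifnot(inherits(task, "classif_task"))
  patients <- unique(task$patient)
  if (length(patients) < 3) stop("need at least 3 patients for LOPO-CV",
                                 call. = FALSE)
  signature <- as.character(signature)
  if (!length(signature) || !all(signature %in% task$feature_names)) {
    stop("signature genes must all be task features", call. = FALSE)
  }
  rows <- lapply(patients, function(p) {
    te_idx <- which(task$patient == p)
    te_y <- task$outcome[te_idx]
    if (length(unique(te_y)) < 2) {
      return(tibble::tibble(patient = p, n_cells = length(te_idx),
                            auc = NA_real_, excluded = TRUE,
                            reason = "single class"))
    }
    tr_idx <- which(task$patient != p)
    df_tr <- data.frame(.y = task$outcome[tr_idx],
                        task$features[tr_idx, signature, drop = FALSE],
                        check.names = FALSE)
    fit <- suppressWarnings(glm(.y ~ ., data = df_tr, family = binomial()))
    df_te <- data.frame(task$features[te_idx, signature, drop = FALSE],
                        check.names = FALSE)
    scores <- suppressWarnings(predict(fit, newdata = df_te,
                                       type = "response"))
    tibble::tibble(patient = p, n_cells = length(te_idx),
                   auc = compute_auc(scores, te_y)$auc,
                   excluded = FALSE, reason = NA_character_)
  })
  per_patient <- dplyr::bind_rows(rows)
  if (all(per_patient$excluded)) {
    stop("no eligible patient: every held-out patient is single-class",
         call. = FALSE)
  }
  aucs <- per_patient$auc[!per_patient$excluded]
  structure(
    list(per_patient = per_patient, median_auc = median(aucs),
         iqr_auc = IQR(aucs), seed = as.integer(seed)),
    class = "lopo_report"
  )
}

#' @export
print.lopo_report <- function(x, ...) {
  n_ex <- sum(x$per_patient$excluded)
  cat("<lopo_report> median per-patient AUC =", signif(x$median_auc, 4),
      "( IQR", signif(x$iqr_auc, 4), ";", n_ex, "patient(s) excluded )\n")
  invisible(x)
}

#' @export
tidy.lopo_report <- function(x, ...) x$per_patient

#' @export
glance.lopo_report <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$per_patient),
    n_excluded = sum(x$per_patient$excluded),
    median_auc = x$median_auc,
    iqr_auc = x$iqr_auc
  )
}

#' Per-patient AUC plot for LOPO-CV
#'
#' @param object A [lopo_cv()] report.
#' @param ... Unused.
#' @return A ggplot of per-patient AUCs with the median marked.
#' @export
autoplot.lopo_report <- function(object, ...) {
  d <- object$per_patient[!object$per_patient$excluded, ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$patient,
                                                     .data$auc),
                                  y = .data$auc)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$median_auc,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "held-out patient", y = "AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  }
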