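#' Build the high-vs-low binary classification task
#'
#' Median-stratum cells are dropped; high-activity cells are labelled 1
#' (case) and low-activity cells 0 (control). Features are the log-normalized
#' expression values of the risk genes present in the data; risk genes
#' missing from the matrix are excluded and recorded.
#'
#' @param data Log-normalized [expr_dataset()].
#' @param labels An `activity_strata` object covering the data's cells.
#' @param risk_genes Character vector of risk-gene ids.
#' @return A list of class `classif_task`: `features` (cell x gene matrix),
#'   `outcome` (integer 0/1), `patient`, `cell_id`, `feature_names`,
#'   `missing_genes`.
#' @export
build_task <- function(data, labels, risk_genes) {
  check_lognorm(data)
  lab <- if (inherits(labels, "activity_strata")) labels$labels else
    tibble::as_tibble(labels)
  lab <- lab[lab$stratum %in% c("low", "high"), , drop = FALSE]
  idx <- match(lab$cell_id, data$cells$cell_id)
  if (anyNA(idx)) stop("strata labels refer to cells absent from the data",
                       call. = FALSE)
  feats <- intersect(risk_genes, data$genes)
  missing <- setdiff(risk_genes, data$genes)
  if (length(missing)) {
    message(length(missing), " risk gene(s) absent from the matrix and ",
            "excluded: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  if (length(feats) == 0) stop("no risk gene present in the data",
                               call. = FALSE)
  outcome <- as.integer(lab$stratum == "high")
  if (sum(outcome == 1) < 2 || sum(outcome == 0) < 2) {
    stop("need at least 2 cells in each of the high and low classes",
         call. = FALSE)
  }
  structure(
    list(
      features = as.matrix(data$values[idx, feats, drop = FALSE]),
      outcome = outcome,
      patient = data$cells$patient[idx],
      cell_id = lab$cell_id,
      feature_names = feats,
      missing_genes = missing
    ),
    class = "classif_task"
  )
}

#' @export
print.classif_task <- function(x, ...) {
  cat("<classif_task> ", length(x$outcome), " cells (",
      sum(x$outcome == 1), " high / ", sum(x$outcome == 0), " low), ",
      length(x$feature_names), " features, ",
      length(unique(x$patient)), " patients\n", sep = "")
  invisible(x)
}

# Subset a task by cell index, keeping all bookkeeping aligned.
task_subset <- function(task, idx) {
  out <- task
  out$features <- task$features[idx, , drop = FALSE]
  out$outcome <- task$outcome[idx]
  out$patient <- task$patient[idx]
  out$cell_id <- task$cell_id[idx]
  out
}

selector_methods <- c("lasso", "rf", "xgb", "gbm", "boruta", "dtree", "abess")

#' Select features with one of seven selectors
#'
#' Method-specific ranked feature lists, each truncated at the method's
#' conventional cutoff: LASSO keeps all non-zero coefficients at the
#' cross-validated penalty; random forest the top 10 by impurity importance;
#' XGBoost and the gradient-boosting configuration the top 20 by gain; the
#' shadow-feature Boruta procedure its confirmed features (top 20 by
#' importance); the decision tree the top 20 by impurity importance; and
#' best-subset (ABESS-type) selection the support chosen by an information
#' criterion. All methods are deterministic under a fixed seed.
#'
#' @param task A [build_task()] result.
#' @param method One of `"lasso"`, `"rf"`, `"xgb"`, `"gbm"`, `"boruta"`,
#'   `"dtree"`, `"abess"`.
#' @param params Optional per-method settings (e.g. `top_k`, `num_trees`,
#'   `nrounds`, `max_iter`, `rf_importance_min` to use an absolute
#'   random-forest importance threshold instead of top-k).
#' @param seed Integer seed.
#' @return Tibble of class `feature_selection` with `feature`, `importance`,
#'   `rank`; attributes `method` and `cutoff`.
#' @export
select_features <- function(task, method, params = list(), seed = 1L) {
  stopifnot(inherits(task, "classif_task"))
  if (!method %in% selector_methods) {
    stop("unknown selection method '", method, "'; expected one of: ",
         paste(selector_methods, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  x <- task$features
  y <- task$outcome
  res <- switch(
    method,
    lasso = {
      cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                              nfolds = params$nfolds %||% 5)
      co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
      if (isTRUE(params$positive_only)) co[co < 0] <- 0
      keep <- co != 0
      tibble::tibble(feature = names(co)[keep], importance = abs(co[keep]),
                     coefficient = co[keep])
    },
    rf = {
      fit <- ranger::ranger(x = x, y = factor(y), num.trees =
                              params$num_trees %||% 500,
                            importance = "impurity",
                            seed = as.integer(seed), num.threads = 1)
      imp <- fit$variable.importance
      d <- tibble::tibble(feature = names(imp), importance = unname(imp))
      if (!is.null(params$rf_importance_min)) {
        d[d$importance > params$rf_importance_min, ]
      } else {
        utils::head(d[order(-d$importance, d$feature), ],
                    params$top_k %||% 10)
      }
    },
    xgb = xgb_importance(x, y, nrounds = params$nrounds %||% 100,
                         eta = 0.3, max_depth = 6, subsample = 1,
                         top_k = params$top_k %||% 20, seed = seed),
    gbm = xgb_importance(x, y, nrounds = params$nrounds %||% 200,
                         eta = 0.05, max_depth = 2, subsample = 0.7,
                         top_k = params$top_k %||% 20, seed = seed),
    boruta = {
      b <- boruta_select(task, max_iter = params$max_iter %||% 30,
                         alpha = params$alpha %||% 0.01, seed = seed,
                         num_trees = params$num_trees %||% 50)
      d <- b[b$decision == "confirmed", c("feature", "mean_importance")]
      names(d)[2] <- "importance"
      utils::head(d[order(-d$importance, d$feature), ],
                  params$top_k %||% 20)
    },
    dtree = {
      df <- data.frame(.y = factor(y), x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      imp <- fit$variable.importance
      if (is.null(imp)) imp <- numeric(0)
      d <- tibble::tibble(feature = names(imp), importance = unname(imp))
      utils::head(d[order(-d$importance, d$feature), ],
                  params$top_k %||% 20)
    },
    abess = {
      a <- abess_select(task, k_max = params$k_max,
                        ic = params$ic %||% "bic")
      tibble::tibble(feature = a$support,
                     importance = abs(a$coefficients))
    }
  )
  res <- res[order(-res$importance, res$feature), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  class(res) <- c("feature_selection", class(res))
  attr(res, "method") <- method
  res
}

# Shared xgboost-based importance ranking; the "gbm" configuration uses
# shallow trees, a small learning rate and row subsampling.
xgb_importance <- function(x, y, nrounds, eta, max_depth, subsample, top_k,
                           seed) {
  fit <- xgb_fit(x, y, nrounds = nrounds, eta = eta, max_depth = max_depth,
                 subsample = subsample, seed = seed)
  imp <- xgboost::xgb.importance(model = fit)
  d <- tibble::tibble(feature = imp$Feature, importance = imp$Gain)
  utils::head(d[order(-d$importance, d$feature), ], top_k)
}

# Thin wrapper over xgb.train (the stable xgboost interface).
xgb_fit <- function(x, y, nrounds, eta = 0.3, max_depth = 6, subsample = 1,
                    seed = 1L) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = eta,
                  max_depth = max_depth, subsample = subsample,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

#' Boruta-type shadow-feature selection
#'
#' Every feature is duplicated and row-permuted into a "shadow" copy; a
#' random forest is fitted on real plus shadow features, and a feature
#' scores a hit when its out-of-bag permutation importance exceeds the
#' maximum shadow importance (out-of-bag importance, unlike impurity
#' importance, gives no lasting credit to chance in-sample label
#' correlations, which the shadow null requires). After
#' each iteration (from the fifth onward) features are confirmed or rejected
#' by a two-sided binomial test of their hit count against chance (p = 0.5)
#' at level `alpha` with Bonferroni correction across features; the loop
#' stops when nothing is tentative or `max_iter` is reached.
#'
#' @param task A [build_task()] result.
#' @param max_iter Maximum iterations (>= 5).
#' @param alpha Significance level of the binomial decision test.
#' @param seed Integer seed.
#' @param num_trees Trees per forest.
#' @return Tibble of class `boruta_result`: `feature`, `decision`
#'   (confirmed/rejected/tentative), `hits`, `n_iter`, `mean_importance`.
#' @export
boruta_select <- function(task, max_iter = 100, alpha = 0.01, seed = 1L,
                          num_trees = 100) {
  stopifnot(inherits(task, "classif_task"))
  if (max_iter < 5) stop("max_iter must be at least 5", call. = FALSE)
  set.seed(as.integer(seed))
  x <- task$features
  y <- factor(task$outcome)
  p <- ncol(x)
  feats <- colnames(x)
  hits <- setNames(integer(p), feats)
  n_tested <- setNames(integer(p), feats)
  imp_sum <- setNames(numeric(p), feats)
  decision <- setNames(rep("tentative", p), feats)
  for (it in seq_len(max_iter)) {
    # rejected features leave the forest (classic behaviour)
    active <- feats[decision != "rejected"]
    xa <- x[, active, drop = FALSE]
    shadow <- apply(xa, 2, sample)
    colnames(shadow) <- paste0(".shadow_", active)
    # keep at least 5 shadows so the max-shadow bar stays meaningful when
    # few real features remain in play
    while (ncol(shadow) < 5) {
      extra <- sample(x[, sample(feats, 1)])
      shadow <- cbind(shadow, extra)
      colnames(shadow)[ncol(shadow)] <- paste0(".shadow_extra",
                                               ncol(shadow))
    }
    # out-of-bag permutation importance: unlike impurity importance it
    # gives ~zero credit to chance in-sample correlations, which is what
    # the shadow comparison needs under the null
    fit <- ranger::ranger(x = cbind(xa, shadow), y = y,
                          num.trees = num_trees,
                          importance = "permutation",
                          seed = sample.int(.Machine$integer.max, 1),
                          num.threads = 1)
    imp <- fit$variable.importance
    shadow_max <- max(imp[startsWith(names(imp), ".shadow_")])
    real_imp <- imp[active]
    hits[active] <- hits[active] + (real_imp > shadow_max)
    n_tested[active] <- n_tested[active] + 1L
    imp_sum[active] <- imp_sum[active] + real_imp
    if (it >= 5) {
      tent <- names(which(decision == "tentative"))
      pvals <- vapply(tent, function(f)
        binom.test(hits[[f]], n_tested[[f]], 0.5)$p.value, numeric(1))
      sig <- pvals * p < alpha  # Bonferroni across features
      frac <- hits[tent] / n_tested[tent]
      decision[tent[sig & frac > 0.5]] <- "confirmed"
      decision[tent[sig & frac < 0.5]] <- "rejected"
      if (!any(decision == "tentative")) break
    }
  }
  out <- tibble::tibble(
    feature = feats,
    decision = unname(decision),
    hits = unname(hits),
    n_iter = unname(n_tested),
    mean_importance = unname(ifelse(n_tested > 0, imp_sum / n_tested, 0))
  )
  class(out) <- c("boruta_result", class(out))
  out
}

# Gram-matrix machinery: RSS of the least-squares fit of y on
# x[, supp] + intercept, evaluated as y'y - b' X'y with b from the normal
# equations, so support search never touches the n-row matrix.
make_rss <- function(x, y) {
  X <- cbind(`(Intercept)` = 1, x)
  G <- crossprod(X)
  g <- drop(crossprod(X, y))
  yty <- sum(y^2)
  function(supp) {
    idx <- c(1L, match(supp, colnames(X)))
    b <- tryCatch(solve(G[idx, idx, drop = FALSE], g[idx]),
                  error = function(e) NULL)
    if (is.null(b)) return(Inf)  # singular support
    max(yty - sum(b * g[idx]), 0)
  }
}

#' Best-subset (ABESS-type) feature selection
#'
#' Adaptive best-subset selection on the linear model of the binary outcome:
#' for each support size `k` the support is found by forward search followed
#' by splicing (swap) refinement on the residual sum of squares, and the
#' size is chosen by an information criterion (BIC by default:
#' `n log(RSS/n) + k log(n)`).
#'
#' @param task A [build_task()] result.
#' @param k_max Largest support size searched (default `min(p, 20)`).
#' @param ic `"bic"` or `"ebic"` (adds `2 k log(p)`).
#' @return A list of class `abess_result`: `support` (selected features,
#'   ordered by absolute coefficient), `coefficients`, `k`, `ic_path` tibble.
#' @export
abess_select <- function(task, k_max = NULL, ic = c("bic", "ebic")) {
  stopifnot(inherits(task, "classif_task"))
  ic <- match.arg(ic)
  x <- task$features
  y <- as.numeric(task$outcome)
  keep <- apply(x, 2, sd) > 0
  x <- x[, keep, drop = FALSE]
  p <- ncol(x)
  n <- nrow(x)
  if (is.null(k_max)) k_max <- min(p, 20L)
  k_max <- min(k_max, p, n - 2L)

  ic_value <- function(rss, k) {
    pen <- k * log(n) + if (ic == "ebic") 2 * k * log(p) else 0
    n * log(rss / n) + pen
  }

  rss_of <- make_rss(x, y)
  supports <- vector("list", k_max + 1)
  rss_path <- numeric(k_max + 1)
  supports[[1]] <- character(0)
  rss_path[1] <- rss_of(character(0))
  supp <- character(0)
  for (k in seq_len(k_max)) {
    # forward step
    cand <- setdiff(colnames(x), supp)
    rss_cand <- vapply(cand, function(f) rss_of(c(supp, f)), numeric(1))
    supp <- c(supp, cand[which.min(rss_cand)])
    best_rss <- min(rss_cand)
    # splicing: swap an in-feature for an out-feature while RSS improves
    pass <- 0L
    repeat {
      pass <- pass + 1L
      improved <- FALSE
      for (f_in in supp) {
        outside <- setdiff(colnames(x), supp)
        if (!length(outside)) break
        alt <- vapply(outside, function(f_out)
          rss_of(c(setdiff(supp, f_in), f_out)), numeric(1))
        if (min(alt) < best_rss - 1e-10) {
          supp <- c(setdiff(supp, f_in), outside[which.min(alt)])
          best_rss <- min(alt)
          improved <- TRUE
          break  # supp changed; restart the sweep
        }
      }
      if (!improved || pass >= 10L) break
    }
    supports[[k + 1]] <- supp
    rss_path[k + 1] <- best_rss
  }
  ics <- vapply(seq_along(rss_path), function(i)
    ic_value(rss_path[i], i - 1L), numeric(1))
  k_best <- which.min(ics) - 1L
  supp <- supports[[k_best + 1]]
  co <- if (k_best == 0) numeric(0) else {
    cf <- stats::lm.fit(cbind(1, x[, supp, drop = FALSE]), y)$coefficients[-1]
    setNames(as.numeric(cf), supp)
  }
  ord <- order(-abs(co), names(co))
  structure(
    list(support = supp[ord], coefficients = co[ord], k = k_best,
         ic_path = tibble::tibble(k = seq_along(ics) - 1L, rss = rss_path,
                                  ic = ics)),
    class = "abess_result"
  )
}

#' Run all seven selectors and form the consensus signature
#'
#' @param task A [build_task()] result.
#' @param params Named list of per-method parameter lists.
#' @param seed Integer seed (shared by all selectors).
#' @return A list of class `selection_report`: `selections` (named list of
#'   [select_features()] tibbles), `consensus` (character vector ordered by
#'   mean rank across selectors), `seed`.
#' @export
consensus_select <- function(task, params = list(), seed = 1L) {
  selections <- lapply(setNames(selector_methods, selector_methods),
                       function(m) {
    select_features(task, m, params = params[[m]] %||% list(), seed = seed)
  })
  structure(
    list(selections = selections,
         consensus = consensus_intersection(selections),
         seed = as.integer(seed)),
    class = "selection_report"
  )
}

#' Intersection of selector feature lists
#'
#' The exact set intersection across all seven selectors, ordered by the
#' mean rank of each feature across the selectors' lists (gene id tiebreak).
#'
#' @param report A `selection_report` or a named list of selection tibbles
#'   covering all seven methods.
#' @return Character vector of consensus features.
#' @export
consensus_intersection <- function(report) {
  sel <- if (inherits(report, "selection_report")) report$selections else
    report
  missing <- setdiff(selector_methods, names(sel))
  if (length(missing)) {
    stop("missing selector list(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lists <- lapply(sel[selector_methods], function(d) d$feature)
  cons <- Reduce(intersect, lists)
  if (length(cons) == 0) return(character(0))
  mean_rank <- vapply(cons, function(f) {
    mean(vapply(sel[selector_methods],
                function(d) d$rank[match(f, d$feature)], numeric(1)))
  }, numeric(1))
  cons[order(mean_rank, cons)]
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> per-selector list sizes:\n")
  sizes <- vapply(x$selections, nrow, integer(1))
  print(sizes)
  cat("consensus (", length(x$consensus), "): ",
      paste(x$consensus, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.selection_report <- function(x, ...) {
  purrr::imap_dfr(x$selections, function(d, m)
    dplyr::mutate(tibble::as_tibble(d), method = m, .before = 1))
}

#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    n_selectors = length(x$selections),
    consensus_size = length(x$consensus),
    seed = x$seed
  )
}

#' Upset-style bar chart of selector list sizes and consensus
#'
#' @param object A [consensus_select()] report.
#' @param ... Unused.
#' @return A ggplot of per-selector list sizes with the consensus size.
#' @export
autoplot.selection_report <- function(object, ...) {
  d <- tibble::tibble(
    method = c(names(object$selections), "consensus"),
    n = c(vapply(object$selections, nrow, integer(1)),
          length(object$consensus))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$method, -.data$n),
                                  y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "features selected") +
    ggplot2::theme_minimal()
}
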