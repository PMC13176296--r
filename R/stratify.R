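#' Stratify cells by composite-score quartiles
#'
#' Cells at or below the 25th percentile of the composite score form the low
#' activity state, cells at or above the 75th percentile the high state, and
#' the rest the median state. Percentiles use the linear-interpolation
#' definition (R quantile type 7). When the quartiles are computed within a
#' cell subset (e.g. one cell type), pass that subset's scores only.
#'
#' @param scoring Named per-cell composite-score vector (>= 4 cells), or an
#'   [score_activity()] panel.
#' @return A list of class `activity_strata`: `labels` tibble (`cell_id`,
#'   `stratum` with levels low/median/high) and cutpoints `q25`, `q75`.
#' @export
stratify_quartiles <- function(scoring) {
  if (inherits(scoring, "activity_panel")) {
    scoring <- setNames(scoring$scoring, scoring$cell_id)
  }
  if (length(scoring) < 4) stop("need at least 4 cells to stratify",
                                call. = FALSE)
  ids <- names(scoring) %||% as.character(seq_along(scoring))
  q25 <- unname(quantile(scoring, 0.25, type = 7))
  q75 <- unname(quantile(scoring, 0.75, type = 7))
  if (q25 == q75 && all(scoring == scoring[1])) {
    warning("all composite scores identical; labelling every cell 'median'",
            call. = FALSE)
    stratum <- rep("median", length(scoring))
  } else {
    stratum <- dplyr::case_when(
      scoring <= q25 ~ "low",
      scoring >= q75 ~ "high",
      TRUE ~ "median"
    )
  }
  structure(
    list(
      labels = tibble::tibble(
        cell_id = ids,
        stratum = factor(stratum, levels = c("low", "median", "high"))
      ),
      q25 = q25, q75 = q75
    ),
    class = "activity_strata"
  )
}

#' Stratify an activity panel, optionally within each cell type
#'
#' With `scope = "cell_type"` (the default) quartiles are computed within
#' each cell type separately, matching an analysis focused on one target
#' population; `scope = "all"` uses a single quartile frame over all cells.
#'
#' @param panel An [score_activity()] panel.
#' @param cells Cell metadata tibble with `cell_id` and `cell_type`.
#' @param scope `"cell_type"` or `"all"`.
#' @return An `activity_strata` object; `cutpoints` is a tibble with one row
#'   per scope group.
#' @export
stratify_activity <- function(panel, cells, scope = c("cell_type", "all")) {
  scope <- match.arg(scope)
  sc <- setNames(panel$scoring, panel$cell_id)
  if (scope == "all") {
    out <- stratify_quartiles(sc)
    out$cutpoints <- tibble::tibble(scope = "all", q25 = out$q25,
                                    q75 = out$q75)
    return(out)
  }
  ct <- setNames(cells$cell_type, cells$cell_id)[names(sc)]
  if (anyNA(ct)) stop("every scored cell needs a cell_type", call. = FALSE)
  pieces <- lapply(split(sc, ct), stratify_quartiles)
  labels <- dplyr::bind_rows(lapply(pieces, function(p) p$labels))
  labels <- labels[match(names(sc), labels$cell_id), ]
  structure(
    list(labels = labels,
         cutpoints = tibble::tibble(
           scope = names(pieces),
           q25 = vapply(pieces, `[[`, numeric(1), "q25"),
           q75 = vapply(pieces, `[[`, numeric(1), "q75"))),
    class = "activity_strata"
  )
}

#' @export
print.activity_strata <- function(x, ...) {
  if (!is.null(x$q25)) {
    cat("<activity_strata> cutpoints q25 =", signif(x$q25, 5),
        ", q75 =", signif(x$q75, 5), "\n")
  } else {
    cat("<activity_strata> per-scope cutpoints:\n")
    print(as.data.frame(x$cutpoints))
  }
  print(table(x$labels$stratum))
  invisible(x)
}

#' @export
tidy.activity_strata <- function(x, ...) x$labels

#' @export
glance.activity_strata <- function(x, ...) {
  tab <- table(x$labels$stratum)
  tibble::tibble(n_cells = nrow(x$labels),
                 n_low = as.integer(tab[["low"]]),
                 n_median = as.integer(tab[["median"]]),
                 n_high = as.integer(tab[["high"]]),
                 q25 = x$q25 %||% NA_real_, q75 = x$q75 %||% NA_real_)
}

#' Ro/e enrichment of activity strata across groups
#'
#' For the stratum x group contingency table of cell counts, the ratio of
#' observed to expected cell numbers, with the chi-square expectation
#' `expected = row_total * col_total / grand_total`. Entries above 1 mark
#' enrichment of a stratum in a group.
#'
#' @param labels An `activity_strata` object (or its `labels` tibble).
#' @param groups Per-cell group labels aligned to the labelled cells, or a
#'   tibble with `cell_id` and `group` to join on.
#' @return A tibble of class `roe_table` in long form: `stratum`, `group`,
#'   `observed`, `expected`, `roe` (`NA` when a stratum or group is empty).
#' @export
roe_enrichment <- function(labels, groups) {
  lab <- if (inherits(labels, "activity_strata")) labels$labels else
    tibble::as_tibble(labels)
  if (is.data.frame(groups)) {
    lab <- dplyr::left_join(lab, groups[, c("cell_id", "group")],
                            by = "cell_id")
    grp <- lab$group
  } else {
    grp <- groups
  }
  if (length(grp) != nrow(lab) || anyNA(grp)) {
    stop("every labelled cell needs a group label", call. = FALSE)
  }
  obs <- table(stratum = lab$stratum, group = grp)
  rt <- rowSums(obs); ct <- colSums(obs); N <- sum(obs)
  exp_tab <- outer(rt, ct) / N
  roe <- ifelse(exp_tab > 0, obs / exp_tab, NA_real_)
  out <- tibble::tibble(
    stratum = rep(rownames(obs), times = ncol(obs)),
    group = rep(colnames(obs), each = nrow(obs)),
    observed = as.vector(obs),
    expected = as.vector(exp_tab),
    roe = as.vector(roe)
  )
  class(out) <- c("roe_table", class(out))
  out
}

#' Heatmap of Ro/e enrichment
#'
#' @param object A [roe_enrichment()] table.
#' @param ... Unused.
#' @return A ggplot tile map of Ro/e by stratum and group.
#' @export
autoplot.roe_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$stratum,
                               fill = .data$roe)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$roe))) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(fill = "Ro/e") +
    ggplot2::theme_minimal()
}
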