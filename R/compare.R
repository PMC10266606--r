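#' Compare per-cell metrics between two labeled groups
#'
#' Convenience wrapper around standard two-sample tests on per-cell values
#' (the default statistical unit for group contrasts). For each metric the
#' helper reports group means and a p-value from either the Mann-Whitney U
#' test or Welch's t-test; `test = "auto"` picks Welch when both groups look
#' normal (Shapiro-Wilk p > 0.05) and Mann-Whitney otherwise. This is a thin
#' reporting helper over off-the-shelf tests, not a core measurement.
#'
#' @param per_cell Combined per-cell tibble holding a grouping column.
#' @param group Name of the grouping column (two levels).
#' @param metrics Character vector of per-cell metric columns.
#' @param test `"auto"`, `"wilcox"` or `"welch"`.
#' @return An `org_group_comparison` object; see [tidy()]/[glance()].
#' @export
compare_groups <- function(per_cell, group = "group",
                           metrics = c("organelle_count", "mean_length_um",
                                       "mean_eccentricity", "mean_rel_dist_pct"),
                           test = c("auto", "wilcox", "welch")) {
  test <- match.arg(test)
  g <- per_cell[[group]]
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("grouping column must have exactly two levels")
  rows <- lapply(intersect(metrics, names(per_cell)), function(m) {
    a <- per_cell[[m]][g == lev[1]]
    b <- per_cell[[m]][g == lev[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    use <- test
    if (test == "auto") {
      normal <- function(x) length(x) >= 3 && length(x) <= 5000 &&
        sd(x) > 0 && shapiro.test(x)$p.value > 0.05
      use <- if (normal(a) && normal(b)) "welch" else "wilcox"
    }
    ht <- if (use == "welch") t.test(a, b) else wilcox.test(a, b, exact = FALSE)
    tibble(metric = m,
           mean_a = mean(a), mean_b = mean(b),
           difference = mean(a) - mean(b),
           n_a = length(a), n_b = length(b),
           test = if (use == "welch") "Welch t" else "Mann-Whitney U",
           p_value = unname(ht$p.value))
  })
  structure(list(results = dplyr::bind_rows(rows),
                 groups = lev, group_col = group, data = per_cell),
            class = "org_group_comparison")
}

#' @export
print.org_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s vs %s (per-cell values)\n",
              x$groups[1], x$groups[2]))
  print(x$results)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x An `org_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return One row per metric: group means, difference, test and p-value.
#' @importFrom generics tidy
#' @export
tidy.org_group_comparison <- function(x, ...) x$results

#' @rdname tidy.org_group_comparison
#' @importFrom generics glance
#' @export
glance.org_group_comparison <- function(x, ...) {
  tibble(n_metrics = nrow(x$results),
         n_cells_a = max(x$results$n_a),
         n_cells_b = max(x$results$n_b),
         min_p_value = min(x$results$p_value))
}

#' @export
generics::tidy

#' @export
generics::glance

#' Boxplots of the compared per-cell metrics
#'
#' @param object An `org_group_comparison`.
#' @param ... Unused.
#' @return A ggplot with one facet per metric.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.org_group_comparison <- function(object, ...) {
  long <- object$data |>
    dplyr::select(dplyr::all_of(c(object$group_col, object$results$metric))) |>
    tidyr::pivot_longer(-dplyr::all_of(object$group_col),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[object$group_col]],
                                     y = .data$value,
                                     fill = .data[[object$group_col]])) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "per-cell value") +
    ggplot2::theme_bw()
}

#' @export
ggplot2::autoplot

#' Distribution plot of one per-cell metric
#'
#' @param per_cell Per-cell tibble (optionally with a grouping column).
#' @param metric Column to plot.
#' @param group Optional grouping column.
#' @return A ggplot boxplot.
#' @export
plot_per_cell <- function(per_cell, metric = "mean_length_um", group = NULL) {
  d <- dplyr::filter(per_cell, !is.na(.data[[metric]]))
  if (is.null(group)) {
    ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data[[metric]])) +
      ggplot2::geom_boxplot(fill = "grey85") +
      ggplot2::labs(x = NULL) + ggplot2::theme_bw()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[group]], y = .data[[metric]],
                                    fill = .data[[group]])) +
      ggplot2::geom_boxplot(show.legend = FALSE) +
      ggplot2::labs(x = NULL) + ggplot2::theme_bw()
  }
}
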