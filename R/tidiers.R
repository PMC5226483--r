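#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [anova_oneway()],
#'   [anova_from_summary()] or [ancova_group_effect()].
#' @param ... Unused.
#' @return A tibble with one row per term (omnibus plus any post hoc
#'   contrasts).
#' @export
tidy.group_comparison <- function(x, ...) {
  rows <- tibble::tibble(
    term = "group", contrast = NA_character_, estimate = NA_real_,
    statistic = x$statistic, df1 = x$df[1], df2 = x$df[2],
    p.value = x$p.value, p.adj = NA_real_
  )
  if (!is.null(x$posthoc)) {
    rows <- dplyr::bind_rows(rows, dplyr::mutate(
      dplyr::select(x$posthoc, "contrast", "estimate", statistic = "t",
                    df2 = "df", "p.value", "p.adj"),
      term = "posthoc", df1 = 1, .before = 1
    ))
  }
  rows
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric, method = x$method, statistic = x$statistic,
                 df1 = x$df[1], df2 = x$df[2], p.value = x$p.value,
                 n = sum(x$group_stats$n), k = nrow(x$group_stats))
}

#' @export
tidy.hub_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot group means of the global metrics
#'
#' Bar-and-error-bar summaries (mean, SD) of each global metric by group —
#' the conventional display for group effects on connectome metrics.
#'
#' @param global_metrics Tibble from [run_pipeline()]'s `global_metrics`
#'   (columns `group` plus metric columns).
#' @param metrics Which metric columns to show (default: all present).
#' @return A ggplot object.
#' @export
plot_global_metrics <- function(global_metrics,
                                metrics = intersect(
                                  c("Cp", "Lp", "Eg", "Eloc", "gamma",
                                    "lambda", "sigma"),
                                  names(global_metrics))) {
  long <- global_metrics |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$metric, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(group = factor(.data$group, c("NC", "SCD", "aMCI")),
                  metric = factor(.data$metric, metrics))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.hub_report <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, .data$betweenness),
                                  y = .data$betweenness)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean nodal betweenness",
                  title = sprintf("Top %d%% betweenness hubs",
                                  round(100 * attr(object, "fraction")))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wmnet_results <- function(object, ...) {
  plot_global_metrics(object$global_metrics)
}

#' Plot group-mean nodal betweenness for selected regions
#'
#' @param nodal Tibble of per-subject nodal metrics (columns `group`,
#'   `label`, `betweenness`).
#' @param regions Region labels to display.
#' @return A ggplot object.
#' @export
plot_nodal_betweenness <- function(nodal, regions) {
  d <- nodal |>
    dplyr::filter(.data$label %in% regions) |>
    dplyr::group_by(.data$group, .data$label) |>
    dplyr::summarise(mean = mean(.data$betweenness),
                     se = sd(.data$betweenness) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(group = factor(.data$group, c("NC", "SCD", "aMCI")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "betweenness centrality") +
    ggplot2::theme_minimal()
}
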