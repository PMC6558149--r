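# ggplot2 views of the main result types.

#' Plot multi-lag entropy curves
#'
#' One line per (channel, metric) curve; with a `group` column (e.g. after
#' averaging curves within class) the lines are coloured by group and the
#' metrics are facetted.
#'
#' @param curves Tibble with columns `tau`, `value`, `metric`, and optionally
#'   `channel` and `group`.
#' @return A ggplot object.
#' @export
plot_entropy_curves <- function(curves) {
  aes_args <- list(x = rlang::sym("tau"), y = rlang::sym("value"))
  if ("group" %in% names(curves)) aes_args$colour <- rlang::sym("group")
  p <- ggplot2::ggplot(curves, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_line(ggplot2::aes(
      group = interaction(
        if ("channel" %in% names(curves)) curves$channel else 1,
        if ("group" %in% names(curves)) curves$group else 1
      )
    ), alpha = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = unique(curves$tau)) +
    ggplot2::labs(x = "embedding delay τ", y = "normalised entropy") +
    ggplot2::theme_minimal()
  if ("metric" %in% names(curves) && length(unique(curves$metric)) > 1) {
    p <- p + ggplot2::facet_wrap(~metric)
  }
  p
}

#' @export
autoplot.ordlag_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object), c("se", "sp", "acc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(
      data = tidyr::pivot_longer(glance(object), dplyr::everything(),
                                 names_to = "metric", values_to = "value"),
      ggplot2::aes(yintercept = .data$value, colour = .data$metric),
      linetype = 2, show.legend = FALSE
    ) +
    ggplot2::labs(x = "fold", y = "percent") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ordinal_distribution <- function(object, ...) {
  df <- tidy(object, drop_zero = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$prob)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(
      x = sprintf("ordinal pattern (m = %d, tau = %d)", object$m, object$tau),
      y = if (object$weighted) "amplitude-weighted probability" else "relative frequency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot SFS feature-selection occurrence counts
#'
#' @param report An `ordlag_cv` returned by [sfs_select()].
#' @param top_n Show at most this many features (default 20).
#' @return A ggplot object.
#' @export
plot_selection_counts <- function(report, top_n = 20) {
  if (is.null(report$selection)) abort("Report carries no selection counts.")
  df <- head(dplyr::arrange(report$selection, dplyr::desc(.data$count)), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data$count),
                                   y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "folds selecting the feature") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
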