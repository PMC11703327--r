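# ggplot2 displays for the result types: correlation grids, median-rank
# league tables, histogram-comparison diagnostics and severity-response
# curves.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_col
#'   geom_step geom_line geom_point facet_wrap labs scale_fill_gradient2
#'   theme_minimal coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot a correlation grid
#'
#' Tile grid of Spearman rho per metric and group, annotated for
#' significant cells (as is conventional for metric-vs-observer tables).
#'
#' @param object A [correlate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moqam_correlations
#' @export
autoplot.moqam_correlations <- function(object, ...) {
  df <- tidy.moqam_correlations(object)
  df$label <- ifelse(df$significant, sprintf("%.2f", df$rho), "")
  ggplot(df, aes(x = .data$metric, y = .data$group, fill = .data$rho)) +
    geom_tile(color = "grey70") +
    geom_text(aes(label = .data$label), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b", mid = "white",
                         high = "#2166ac", na.value = "grey90") +
    labs(x = NULL, y = NULL, fill = "Spearman\nrho",
         title = "Metric-observer correlation (labels: p < 0.05)") +
    theme_minimal()
}

#' Plot the median-rank league table
#'
#' @param object A [rank_metrics()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moqam_ranks
#' @export
autoplot.moqam_ranks <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$metric <- factor(df$metric, levels = rev(df$metric))
  ggplot(df, aes(x = .data$metric, y = .data$median_rank)) +
    geom_col(fill = "#2166ac") +
    coord_flip() +
    labs(x = NULL, y = "Median rank of |rho| across groups (1 = strongest)") +
    theme_minimal()
}

#' Plot the normalization histogram diagnostic
#'
#' Paired image/reference intensity histograms within the brain mask for
#' each normalization mode, with the intersection coefficient in the panel
#' label.
#'
#' @param object A [histogram_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moqam_hist_report
#' @export
autoplot.moqam_hist_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(panel = sprintf("%s (overlap %.2f)", .data$norm_mode,
                                  .data$overlap)) |>
    tidyr::unnest("hist") |>
    tidyr::pivot_longer(c("p_image", "p_reference"),
                        names_to = "which", values_to = "p",
                        names_prefix = "p_")
  ggplot(df, aes(x = .data$mid, y = .data$p, color = .data$which)) +
    geom_step() +
    facet_wrap(~panel, scales = "free") +
    labs(x = "intensity (normalized)", y = "probability", color = NULL) +
    theme_minimal()
}

#' Plot metric values against corruption severity
#'
#' One line per metric (facets free-scaled), useful to inspect the
#' monotone response of each metric along the severity ladder of a
#' synthetic study.
#'
#' @param study_table An [evaluate_dataset()] result whose manifest
#'   carried a `severity` column.
#' @return A ggplot object.
#' @export
plot_severity_response <- function(study_table) {
  stopifnot("severity" %in% names(study_table))
  df <- dplyr::filter(tibble::as_tibble(study_table),
                      .data$available, is.finite(.data$value))
  ggplot(df, aes(x = .data$severity, y = .data$value, group = .data$image_id)) +
    geom_point(alpha = 0.4) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "corruption severity", y = "metric value") +
    theme_minimal()
}
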