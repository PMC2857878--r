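# ggplot2 visualizations for enrichment and connectivity results.

#' Enrichment plot for a scored gene set
#'
#' The classic running-sum ("mountain") plot: the enrichment profile along
#' the ranked list, a rug of the set's hit positions, and the peak that
#' defines the ES.
#'
#' @param object An `enrichment_result` from [enrichment_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble(position = seq_along(object$running_sum), running = object$running_sum)
  hits <- tibble(position = object$hit_index)
  peak <- tibble(position = object$peak_index, running = object$es)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(
      data = hits, ggplot2::aes(x = .data$position),
      inherit.aes = FALSE, sides = "b", length = ggplot2::unit(0.04, "npc"),
      alpha = 0.5
    ) +
    ggplot2::geom_point(data = peak, colour = "#d95f02", size = 2) +
    ggplot2::labs(
      title = object$set_name,
      subtitle = sprintf("ES = %.3f (set size %d)", object$es, object$size),
      x = "rank in ordered list", y = "running enrichment score"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.enrichment_result
#' @param x An `enrichment_result`.
#' @export
plot_enrichment <- function(x, ...) autoplot.enrichment_result(x, ...)

#' Connectivity-score overview for a study comparison
#'
#' Bar chart of the connectivity score per signature, with the underlying
#' up/down enrichment scores overlaid as points.
#'
#' @param comparison A `study_comparison` tibble from [compare_studies()].
#' @return A ggplot object.
#' @export
plot_connectivity <- function(comparison) {
  stopifnot(is.data.frame(comparison), all(c("study", "cs") %in% names(comparison)))
  df <- dplyr::filter(comparison, !is.na(.data$cs))
  long <- tidyr::pivot_longer(
    df[c("study", "es_up", "es_down")],
    cols = c("es_up", "es_down"),
    names_to = "direction", values_to = "es"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$study, .data$cs))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$cs), fill = "#2c7fb8", alpha = 0.8) +
    ggplot2::geom_point(
      data = long,
      ggplot2::aes(y = .data$es, shape = .data$direction),
      colour = "#d95f02"
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "connectivity score (bars) / ES (points)",
      shape = NULL
    ) +
    ggplot2::theme_minimal()
}
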