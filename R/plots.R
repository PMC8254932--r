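# ggplot2 views of the main result types.

#' @method autoplot aggregate_heatmap
#' @export
autoplot.aggregate_heatmap <- function(object, ...) {
  df <- as_tibble(object$matrix, .name_repair = ~ as.character(seq_along(.x))) %>%
    mutate(row = row_number()) %>%
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "mean_count") %>%
    mutate(col = as.integer(.data$col))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$mean_count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "mean count") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Aggregate intra-TAD contacts (n = %d)", object$n_tads)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot distance_model
#' @export
autoplot.distance_model <- function(object, ...) {
  df <- object$strata %>% mutate(mid = sqrt(.data$lo * .data$hi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$mean_count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "TAD midpoint separation (bp)",
                  y = "mean TAD-pair contact count",
                  size = "pairs") +
    ggplot2::theme_minimal()
}

#' Bar chart of TAD clique-size categories
#'
#' @param stats Tibble from [assign_clique_stats()].
#' @return A ggplot object.
#' @export
plot_clique_categories <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "firebrick") +
    ggplot2::labs(x = "maximal clique size category", y = "TADs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Ratio of clique size to degree + 1 by category
#'
#' Mirrors the per-category distribution of `k / (degree + 1)`: singletons sit
#' at exactly 1 and the ratio decreases as TADs in larger cliques engage in
#' more interactions outside their clique.
#'
#' @param stats Tibble from [assign_clique_stats()].
#' @return A ggplot object.
#' @export
plot_clique_ratio <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$category, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::labs(x = "maximal clique size category", y = "k / (degree + 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
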