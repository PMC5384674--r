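#' Module size distribution
#'
#' @param partition A `module_partition`.
#' @return A ggplot histogram of module sizes, with small-flagged modules
#'   highlighted.
#' @export
plot_module_sizes <- function(partition) {
  sizes <- partition %>%
    distinct(.data$module_id, .data$module_size, .data$small)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$module_size,
                                      fill = .data$small)) +
    ggplot2::geom_histogram(bins = 30, colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "orange"),
                               name = "below min size") +
    ggplot2::labs(x = "module size (proteins)", y = "modules") +
    ggplot2::theme_minimal()
}

#' Heat map of combined module similarities
#'
#' @param sim_records Tibble from [module_similarity()].
#' @return A ggplot tile map of the combined score.
#' @export
plot_similarity_heatmap <- function(sim_records) {
  mods <- sort(unique(c(sim_records$module_a, sim_records$module_b)))
  full <- bind_rows(
    sim_records %>% select(x = "module_a", y = "module_b", combined = "combined"),
    sim_records %>% select(x = "module_b", y = "module_a", combined = "combined"),
    tibble(x = mods, y = mods, combined = 1)
  )
  ggplot2::ggplot(full, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$combined)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "combined") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Observed vs null target-seed distance distributions
#'
#' @param object A `proximity_result`.
#' @param ... Unused.
#' @return A ggplot of the two distance distributions.
#' @method autoplot proximity_result
#' @export
autoplot.proximity_result <- function(object, ...) {
  obs <- object$observed$distance[is.finite(object$observed$distance)]
  pooled <- unlist(object$null_distances)
  pooled <- pooled[is.finite(pooled)]
  df <- bind_rows(tibble(distance = obs, set = "drug targets"),
                  tibble(distance = pooled, set = "randomized"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$set)) +
    ggplot2::geom_bar(ggplot2::aes(y = ggplot2::after_stat(prop)),
                      position = "dodge", width = 0.7) +
    ggplot2::labs(x = "hop distance to nearest seed gene",
                  y = "fraction of proteins") +
    ggplot2::scale_fill_manual(values = c("drug targets" = "steelblue",
                                          "randomized" = "grey60"),
                               name = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
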