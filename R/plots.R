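#' Heatmap of a group-wise distance table
#'
#' Tiles the mean shortest distances between groups (including the random
#' baselines); significant cells can be read off the printed values.
#'
#' @param object A `distance_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_b, y = .data$group_a,
                                   fill = .data$mean_distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mean_distance)),
                       colour = "white", size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(direction = -1, na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean\ndistance",
                  title = "Average shortest distances between groups") +
    ggplot2::theme_minimal()
}

#' Dot plot of an enrichment result
#'
#' Shows the reported terms ordered by adjusted significance, point size
#' giving the overlap.
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms to display (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 20L, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No enriched terms"))
  }
  df$term_name <- factor(df$term_name, levels = rev(unique(df$term_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adjusted),
                                   y = .data$term_name,
                                   size = .data$overlap,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  title = "Over-representation analysis") +
    ggplot2::theme_minimal()
}

#' Score profile of an RWR run
#'
#' Ranked visitation scores on a log scale, seeds highlighted.
#'
#' @param object An `rwr_scores` object.
#' @param top Number of genes to display (default 100).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rwr_scores <- function(object, top = 100L, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   colour = .data$is_seed)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "RWR score",
                  title = "Random walk with restart visitation scores") +
    ggplot2::theme_minimal()
}

#' Null distribution of a neighborhood overlap test
#'
#' Histogram of the overlaps observed under label permutation, with the
#' real overlap marked.
#'
#' @param object An `overlap_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_test <- function(object, ...) {
  df <- tidy.overlap_test(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_overlap)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$real_overlap,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "neighborhood overlap under label permutation",
                  y = "count",
                  title = sprintf("%s vs %s: real overlap %d, p_low = %.3g",
                                  object$group_a, object$group_b,
                                  object$real_overlap, object$p_low)) +
    ggplot2::theme_minimal()
}
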