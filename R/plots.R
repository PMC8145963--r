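#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_step labs scale_fill_gradient2 theme_minimal
NULL

#' Heatmap of the lipid-lipid correlation structure
#'
#' Species ordered by the clustering dendrogram, tiles colored by
#' correlation coefficient.
#'
#' @param object A `lipid_corr` from [correlation_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lipid_corr <- function(object, ...) {
  ord <- object$hclust$labels[object$hclust$order]
  d <- tidy(object)
  d$species1 <- factor(d$species1, levels = ord)
  d$species2 <- factor(d$species2, levels = ord)
  ggplot(d, aes(x = .data$species1, y = .data$species2,
                fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Out-of-bag error trace of backward feature elimination
#'
#' @param object A `marker_panel` from [rf_select_markers()].
#' @param ... Unused.
#' @return A ggplot object showing OOB error against panel size, with
#'   the selected panel marked.
#' @export
autoplot.marker_panel <- function(object, ...) {
  d <- object$trace
  sel <- d[which.min(abs(d$oob_error - object$oob_error) +
                       (d$n_features != length(object$panel))), ]
  ggplot(d, aes(x = .data$n_features, y = .data$oob_error)) +
    geom_step() +
    geom_point(data = sel, color = "red", size = 2) +
    ggplot2::scale_x_reverse() +
    labs(x = "Features remaining", y = "OOB error") +
    theme_minimal()
}

#' Growth curves colored by condition
#'
#' @param od_table Wide OD table (`time_min` + sample columns).
#' @param metadata Optional metadata with `sample_id` and `butanol`.
#' @param n Plot at most this many curves (default 24).
#' @return A ggplot object (log OD600 vs time).
#' @export
plot_growth_curves <- function(od_table, metadata = NULL, n = 24) {
  long <- tidyr::pivot_longer(as_tibble(od_table), cols = -"time_min",
                              names_to = "sample_id", values_to = "od")
  keep <- utils::head(unique(long$sample_id), n)
  long <- long[long$sample_id %in% keep, ]
  p <- ggplot(long, aes(x = .data$time_min / 60, y = .data$od,
                        group = .data$sample_id))
  if (!is.null(metadata)) {
    long <- dplyr::left_join(long, as_tibble(metadata), by = "sample_id")
    p <- ggplot(long, aes(x = .data$time_min / 60, y = .data$od,
                          group = .data$sample_id,
                          color = factor(.data$butanol)))
  }
  p + geom_line(alpha = 0.6) + ggplot2::scale_y_log10() +
    labs(x = "Time (h)", y = "OD600", color = "butanol") +
    theme_minimal()
}
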