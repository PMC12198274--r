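#' Plot group-conditioned networks
#'
#' Draws every group's network with a shared Fruchterman-Reingold layout and
#' a shared edge-weight scale (the maximum absolute weight across groups),
#' so edge thickness is comparable between panels.
#'
#' @param object A [fit_mgm()] result.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moderated_mgm <- function(object, seed = 1, ...) {
  layout <- layout_positions(object, seed = seed)
  max_w <- max(vapply(object$conditioned, function(m) max(abs(m)), numeric(1)))
  if (max_w == 0) max_w <- 1
  edges <- tidy(object)
  edges <- edges[edges$weight != 0, ]
  edges <- dplyr::left_join(edges, layout, by = c(item_i = "node"))
  edges <- dplyr::rename(edges, x = "x", y = "y")
  edges <- dplyr::left_join(edges, layout, by = c(item_j = "node"),
                            suffix = c("", "end"))
  nodes <- tidyr::crossing(layout, group = factor(object$groups,
                                                  levels = object$groups))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$weight),
                   color = .data$weight > 0),
      alpha = 0.7, show.legend = FALSE
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 6, shape = 21, fill = "grey90") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node), size = 2) +
    ggplot2::scale_linewidth_continuous(limits = c(0, max_w),
                                        range = c(0.1, 2)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#2166AC",
                                           `FALSE` = "#B2182B")) +
    ggplot2::facet_wrap(~group) +
    ggplot2::theme_void()
}

#' Plot standardized local network metrics
#'
#' Dot plot of z-scored node strength and local clustering per node, colored
#' by group.
#'
#' @param object A [local_metrics()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.local_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("strength_z", "clustering_z"),
                              names_to = "metric", values_to = "z")
  long$metric <- dplyr::recode(long$metric, strength_z = "node strength",
                               clustering_z = "local clustering")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$node,
                                     color = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = .data$node), color = "grey80") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "standardized metric", y = NULL, color = "group") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap stability of moderation effects
#'
#' Horizontal bars of bootstrap presence proportions per moderated edge with
#' the moderate (0.50) and good (0.80) stability thresholds marked.
#'
#' @param object A [moderation_stability()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_report <- function(object, ...) {
  d <- as_tibble(object)
  if (!nrow(d)) abort("empty stability report.")
  d$edge <- paste0(d$item_i, "-", d$item_j, " (", d$group, ")")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$proportion,
                                  y = stats::reorder(.data$edge,
                                                     .data$proportion),
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(0.5, 0.8), linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "bootstrap presence proportion", y = NULL,
                  fill = "stability") +
    ggplot2::theme_minimal()
}
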