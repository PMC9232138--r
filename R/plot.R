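#' Trajectory heat map
#'
#' Draws the simulation as a state-by-node heat map (steps on the x axis,
#' nodes on the y axis in declaration order, tile color = level), the
#' standard way trajectories of logical cell-cycle models are displayed.
#' Attractor states are marked along the top edge.
#'
#' @param object A `yc_trajectory`.
#' @param nodes Optional subset/order of nodes to show (default: all, in
#'   model order; phenomenological nodes first make cycle reading easiest).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.yc_trajectory <- function(object, nodes = NULL, ...) {
  node_names <- attr(object, "node_names")
  if (is.null(nodes)) nodes <- node_names
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "step",
                  dplyr::all_of(nodes), "in_attractor"),
    cols = dplyr::all_of(nodes),
    names_to = "node", values_to = "level")
  long$node <- factor(long$node, levels = rev(nodes))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$node,
                                     fill = factor(.data$level))) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.1) +
    ggplot2::geom_point(
      data = dplyr::distinct(long[long$in_attractor, ], .data$step),
      ggplot2::aes(x = .data$step, y = length(nodes) + 0.7),
      inherit.aes = FALSE, shape = 18, size = 1.2) +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey95", `1` = "#a6cee3", `2` = "#1f78b4",
                 `3` = "#08306b"),
      name = "level") +
    ggplot2::labs(x = "simulation step", y = NULL,
                  title = attr(object, "model_name"),
                  subtitle = paste0("attractor: ",
                                    attr(object, "attractor")$kind)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Ensemble outcome barplot
#'
#' @param x A `yc_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ensemble <- function(x, ...) {
  stopifnot(inherits(x, "yc_ensemble"))
  d <- tidy.yc_ensemble(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$proportion)) +
    ggplot2::geom_col(fill = "#1f78b4") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "fraction of runs",
                  title = sprintf("%d runs, %.1f%% functional cycles",
                                  x$n_runs, 100 * x$functional_fraction)) +
    ggplot2::theme_minimal(base_size = 10)
}
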