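# ggplot2 visualisations: network rendering over a layout, the sub-network
# census quadrant plot, the super-enhancer rank curve, and the interaction
# distance distribution.

#' @noRd
state_palette <- function() {
  c(active = "#8dd35f", h3k4me1_only = "#1a7a1a", bivalent = "#f5a623",
    polycomb = "#d0021b", heterochromatin = "#7b2d8b",
    unclassified = "#9b9b9b", background = "#d8d8d8", mixed = "#4a90d9")
}

#' Plot a laid-out network
#'
#' Draws edges between laid-out nodes and the nodes themselves, sized by
#' degree (monotone mapping) and coloured by a node attribute.
#'
#' @param object a `canvas_layout`.
#' @param net the `canvas_network` the layout was computed on.
#' @param colour_by node column to colour by: `"specificity"`, `"state"` or
#'   `"expression"` (the column must be present on `net$nodes`).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.canvas_layout <- function(object, net, colour_by = "specificity",
                                   ...) {
  if (!colour_by %in% names(net$nodes)) {
    abort(sprintf("unknown styling key '%s'", colour_by))
  }
  pos <- tibble(fragment_id = object$node, x = object$x, y = object$y)
  nodes <- net$nodes |> inner_join(pos, by = "fragment_id")
  seg <- net$edges |>
    inner_join(pos |> rename(x1 = "x", y1 = "y"),
               by = c(node1 = "fragment_id")) |>
    inner_join(pos |> rename(x2 = "x", y2 = "y"),
               by = c(node2 = "fragment_id"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2),
      colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree,
                   colour = .data[[colour_by]])) +
    ggplot2::scale_size_continuous(range = c(0.5, 4)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = colour_by, size = "degree")
  if (colour_by %in% c("state", "expression")) {
    pal <- state_palette()
    if (colour_by == "state") {
      p <- p + ggplot2::scale_colour_manual(values = pal, na.value = "grey50")
    }
  }
  p
}

#' Render a network figure to file
#'
#' @param net `canvas_network`.
#' @param layout `canvas_layout`.
#' @param path output image path (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @param colour_by node styling key (see [autoplot.canvas_layout()]).
#' @param width,height size in inches.
#' @return `path`, invisibly.
#' @export
render_static <- function(net, layout, path, colour_by = "specificity",
                          width = 7, height = 7) {
  p <- autoplot(layout, net = net, colour_by = colour_by)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Sub-network census quadrant plot
#'
#' @param census tibble from [subnetwork_census()].
#' @return A ggplot: per-condition edge counts against each other, points
#'   coloured by quadrant.
#' @export
plot_census <- function(census) {
  ggplot2::ggplot(census,
                  ggplot2::aes(x = .data$edges_A, y = .data$edges_B,
                               colour = .data$quadrant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "edges supported in A", y = "edges supported in B") +
    ggplot2::theme_minimal()
}

#' Super-enhancer rank curve
#'
#' @param elements output of [call_super_enhancers()].
#' @return A ggplot of signal against rank with the cutoff marked.
#' @export
plot_rank_curve <- function(elements) {
  cutoff <- attr(elements, "cutoff_signal")
  ggplot2::ggplot(elements,
                  ggplot2::aes(x = .data$rank, y = .data$signal,
                               colour = .data$is_super)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "#d0021b")) +
    ggplot2::labs(x = "rank (ascending signal)", y = "stitched signal",
                  colour = "super-enhancer") +
    ggplot2::theme_minimal()
}

#' Interaction distance distribution by band
#'
#' Distances are plotted per condition and band; Tukey-style outliers
#' (beyond 1.5 x IQR from the quartiles) are flagged by the boxplot but all
#' values remain in the underlying statistics.
#'
#' @param net `canvas_network`.
#' @param bands band breakpoints (see [classify_distance_band()]).
#' @return A ggplot.
#' @export
plot_distance_bands <- function(net, bands = c(short = 250000, long = 1000000)) {
  d <- bind_rows(
    net$edges |> filter(!.data$trans, edge_supported(.data$specificity, "A")) |>
      mutate(condition = net$conditions[["A"]]),
    net$edges |> filter(!.data$trans, edge_supported(.data$specificity, "B")) |>
      mutate(condition = net$conditions[["B"]])
  ) |>
    mutate(band = classify_distance_band(.data$distance, bands))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$distance,
                                  fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance band", y = "linear genomic distance (bp)") +
    ggplot2::theme_minimal()
}
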