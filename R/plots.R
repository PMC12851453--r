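#' Plot a resemblance graph
#'
#' Draws the agents on a fixed layout and connects pairs whose resemblance
#' clears the weak tier, line width proportional to z, solid for the
#' strong tier and dashed for the weak, coloured by tie category. Requires
#' ggplot2.
#'
#' @param graph Output of [resemblance_graph()].
#' @param factor Factor to draw.
#' @return A ggplot object.
#' @export
plot_resemblance_graph <- function(graph, factor) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_resemblance_graph() needs the ggplot2 package", call. = FALSE)
  }
  layout <- tibble::tibble(
    role = cultnet_roles(),
    x = c(0, 0.6, -1, 1, -1.5, 1.5, -2, -1.2, 1.2, 2),
    y = c(0, -0.4, 1, 1, 0, 0, 2, 2, 2, 2)
  )
  e <- graph$edges[graph$edges$factor == factor & graph$edges$tier != "none", ]
  e <- dplyr::left_join(e, setNames(layout, c("role_a", "xa", "ya")),
                        by = "role_a")
  e <- dplyr::left_join(e, setNames(layout, c("role_b", "xb", "yb")),
                        by = "role_b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$z,
                   colour = .data$category, linetype = .data$tier)
    ) +
    ggplot2::scale_linetype_manual(
      values = c(strong = "solid", weak = "dashed")
    ) +
    ggplot2::geom_label(
      data = layout, ggplot2::aes(x = .data$x, y = .data$y, label = .data$role),
      size = 2.6
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5)) +
    ggplot2::labs(title = factor) +
    ggplot2::theme_void()
}

#' Plot transmission coefficients with bootstrap intervals
#'
#' Bar chart of the trait-polarity `B_i` per parental type with their
#' bootstrap confidence intervals. Requires ggplot2.
#'
#' @param tables One or more [bootstrap_ci()] outputs, row-bound.
#' @return A ggplot object.
#' @export
plot_transmission <- function(tables) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_transmission() needs the ggplot2 package", call. = FALSE)
  }
  d <- tables[tables$polarity == "trait", ]
  d$type <- factor(d$type, levels = parental_type_levels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$B)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2
    ) +
    ggplot2::facet_wrap(~factor) +
    ggplot2::labs(x = "parental type", y = "proportion of students with trait")
}

#' Plot bias estimates in the bias triangle
#'
#' Scatter of normalised (Vertical, Horizontal, Other) bias weights inside
#' the 2-simplex, one point per factor and polarity. Requires ggplot2.
#'
#' @param coords Output of [triangle_coords()].
#' @return A ggplot object.
#' @export
plot_bias_triangle <- function(coords) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bias_triangle() needs the ggplot2 package", call. = FALSE)
  }
  corners <- tibble::tibble(
    x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0)
  )
  labels <- tibble::tibble(
    x = c(-0.04, 1.04, 0.5), y = c(-0.04, -0.04, sqrt(3) / 2 + 0.05),
    lab = c("VertB", "HorizB", "OtherB")
  )
  ggplot2::ggplot() +
    ggplot2::geom_path(data = corners, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(
      data = coords,
      ggplot2::aes(.data$x, .data$y, colour = .data$factor,
                   shape = .data$polarity),
      size = 2.5
    ) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(.data$x, .data$y, label = .data$lab)) +
    ggplot2::theme_void()
}
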