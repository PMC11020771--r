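# ggplot2 views of meshes, strain fields and intervals summaries.

#' @describeIn planar_mesh Mesh wireframe plot.
#' @param object A `planar_mesh`.
#' @exportS3Method
autoplot.planar_mesh <- function(object, ...) {
  tri <- object$triangles
  poly <- tibble(
    element = rep(seq_len(nrow(tri)), each = 3),
    x = object$nodes[t(tri), 1],
    y = object$nodes[t(tri), 2])
  ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y,
                                     group = .data$element)) +
    ggplot2::geom_polygon(fill = "grey92", colour = "grey40",
                          linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @describeIn solve_fea Equivalent-strain contour map (element fill).
#' @param object An `fea_result`.
#' @param field Strain column to map (default `"eps_eq"`; use
#'   `"eps_signed"` for the tensile/compressive map).
#' @exportS3Method
autoplot.fea_result <- function(object, field = "eps_eq", ...) {
  tri <- object$mesh$triangles
  poly <- tibble(
    element = rep(seq_len(nrow(tri)), each = 3),
    x = object$mesh$nodes[t(tri), 1],
    y = object$mesh$nodes[t(tri), 2],
    value = rep(object$strains[[field]], each = 3))
  ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y,
                                     group = .data$element,
                                     fill = .data$value)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_viridis_c(name = paste0(field, " (με)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Intervals bar chart
#'
#' Percent model area per strain interval, one bar group per taxon — the
#' standard comparative view of intervals-method output.
#'
#' @param intervals_table Wide tibble (`taxon_id`, `V1`, `V2`, ...), as
#'   produced by [run_pipeline()].
#' @return A ggplot.
#' @export
plot_intervals <- function(intervals_table) {
  long <- tidyr::pivot_longer(intervals_table, -"taxon_id",
                              names_to = "interval",
                              values_to = "percent_area")
  ggplot2::ggplot(long, ggplot2::aes(.data$interval, .data$percent_area,
                                     fill = .data$taxon_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "strain interval (V1 lowest)",
                  y = "% of model area", fill = NULL) +
    ggplot2::theme_minimal()
}
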