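# ggplot2 displays for the main result types.

#' @export
autoplot.xi_dynamics <- function(object, every = 1L, ...) {
  d <- tidy(object)
  keep <- unique(d$seed)[seq(1L, length(unique(d$seed)), by = every)]
  d <- d[d$seed %in% keep, ]
  ring <- tibble::tibble(pd = object$outline_xi[, 1L], ap = object$outline_xi[, 2L])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xi_pd, y = .data$xi_ap, group = .data$seed)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$xi0_ap), linewidth = 0.3, alpha = 0.7) +
    ggplot2::geom_polygon(data = ring, ggplot2::aes(x = .data$pd, y = .data$ap),
                          inherit.aes = FALSE, fill = NA, colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(xi[PD]), y = expression(xi[AP]),
                  colour = expression(xi["0,AP"]),
                  title = "Rescaled (xi-space) cell trajectories") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stage_distance <- function(object, ...) {
  d <- tidy(object)
  maps <- composite_stage_maps(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_a, y = .data$t_b, fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tidy(maps$ab),
                        ggplot2::aes(x = .data$t_source, y = .data$t_target),
                        inherit.aes = FALSE, colour = "white", size = 0.8) +
    ggplot2::geom_point(data = tidy(maps$ba),
                        ggplot2::aes(x = .data$t_target, y = .data$t_source),
                        inherit.aes = FALSE, colour = "black", size = 0.8) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = paste("stage,", object$species_a),
                  y = paste("stage,", object$species_b),
                  fill = expression(delta),
                  title = "Stage-pair trajectory distance") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.region_scan <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(c("min_eta", "cv"), names_to = "statistic", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = expression(alpha~"(distal fraction retained)"), y = NULL,
                  title = "Region-restricted fit and overfitting") +
    ggplot2::theme_minimal()
}

#' Spatial pattern of local deformation
#'
#' Plots the local area-growth ratio (fill) and the anisotropy orientation
#' (segments whose length scales with the anisotropy magnitude) of a map
#' between two stages, on a lattice over the initial outline.
#'
#' @param map A deformation map.
#' @param outline Initial [tissue_outline()]; defaults to the map's own.
#' @param t Stage at which to evaluate F (reference = initial configuration).
#' @param n_grid Lattice resolution.
#' @param segment_scale Length of an anisotropy segment per unit log stretch
#'   ratio, in micrometres.
#' @return A ggplot object.
#' @export
plot_deformation_field <- function(map, t, outline = NULL, n_grid = 20L,
                                   segment_scale = NULL) {
  outline <- outline %||% initial_outline(map)
  qp <- quad_points(outline_ring(outline), n_grid)
  Fq <- deformation_gradient(map, qp$points, t)
  summ <- local_deformation_summary(Fq)
  pos <- evaluate_map(map, qp$points, t)
  d <- dplyr::bind_cols(tibble::tibble(pd = pos[, 1L], ap = pos[, 2L]), summ)
  if (is.null(segment_scale)) {
    segment_scale <- 0.25 * sqrt(poly_area(outline_ring(outline)) / nrow(d))
  }
  len <- segment_scale * d$anisotropy
  ang <- ifelse(is.na(d$orientation), 0, d$orientation)
  seg <- dplyr::mutate(d,
                       xend = .data$pd + len * cos(ang), yend = .data$ap + len * sin(ang),
                       x0 = .data$pd - len * cos(ang), y0 = .data$ap - len * sin(ang))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pd, y = .data$ap)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$area_ratio), size = 2) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.4) +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "P-D (um)", y = "A-P (um)", colour = "area ratio",
                  title = sprintf("Local deformation at stage %.3g", t)) +
    ggplot2::theme_minimal()
}
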