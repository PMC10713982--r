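#' Read a labeled-spot table
#'
#' Spot tables record the measured positions of fluorescently labeled tissue
#' spots: one row per (individual, spot, stage) with the position on the
#' frontal plane in micrometres. Axis 1 (`pd_um`) is the proximo-distal axis
#' with distal positive; axis 2 (`ap_um`) is the antero-posterior axis with
#' anterior positive.
#'
#' @param path Path to a CSV or TSV file with header columns
#'   `individual_id`, `stage`, `spot_id`, `pd_um`, `ap_um`.
#' @param delim Field delimiter; guessed from the file extension by default.
#' @param flip_ap If `TRUE`, negate the A-P coordinate on read. Species imaged
#'   with the posterior side up can be brought onto the shared
#'   anterior-positive convention this way.
#' @return A tibble with the five schema columns, rows in file order.
#' @export
read_spot_table <- function(path, delim = NULL, flip_ap = FALSE) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE)
  required <- c("individual_id", "stage", "spot_id", "pd_um", "ap_um")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(paste0("spot table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "morphodyn_schema_error")
  }
  out <- tibble::tibble(
    individual_id = as.character(raw$individual_id),
    stage = as.numeric(raw$stage),
    spot_id = as.character(raw$spot_id),
    pd_um = as.numeric(raw$pd_um),
    ap_um = if (flip_ap) -as.numeric(raw$ap_um) else as.numeric(raw$ap_um)
  )
  validate_spot_table(out)
  out
}

#' Write a labeled-spot table
#'
#' @param spots A spot tibble as returned by [read_spot_table()] or
#'   [sample_spots()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  validate_spot_table(spots)
  df <- as.data.frame(spots[, c("individual_id", "stage", "spot_id", "pd_um", "ap_um")])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a spot table against its invariants
#'
#' Checks finiteness of stages and coordinates and uniqueness of
#' (individual, spot, stage) keys; errors with a classed condition naming
#' the offending row.
#'
#' @param spots A spot tibble.
#' @return The input, invisibly.
#' @export
validate_spot_table <- function(spots) {
  bad <- which(!is.finite(spots$stage) | !is.finite(spots$pd_um) | !is.finite(spots$ap_um))
  if (length(bad) > 0L) {
    abort(paste0("non-finite stage or coordinate at row(s): ",
                 paste(utils::head(bad, 5L), collapse = ", ")),
          class = "morphodyn_value_error")
  }
  key <- paste(spots$individual_id, spots$spot_id, spots$stage, sep = "\r")
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (individual_id, spot_id, stage) at row ",
                 anyDuplicated(key)),
          class = "morphodyn_value_error")
  }
  invisible(spots)
}

#' Stage grid
#'
#' A strictly increasing vector of stage values on one species' own staging
#' scale. Consecutive stages delimit the time intervals over which per-interval
#' deformation maps are fitted.
#'
#' @param species Species label.
#' @param stages Strictly increasing numeric vector of stage values.
#' @return An object of class `stage_grid`.
#' @export
stage_grid <- function(species, stages) {
  stages <- as.numeric(stages)
  if (length(stages) < 2L || anyNA(stages) || any(diff(stages) <= 0)) {
    abort("stages must be a strictly increasing numeric vector of length >= 2",
          class = "morphodyn_value_error")
  }
  structure(list(species = as.character(species), stages = stages),
            class = "stage_grid")
}

#' @export
print.stage_grid <- function(x, ...) {
  cat("<stage_grid> ", x$species, ": ", length(x$stages), " stages in [",
      min(x$stages), ", ", max(x$stages), "]\n", sep = "")
  invisible(x)
}

#' Tissue outline
#'
#' @param polygon An n x 2 matrix (or data frame) of outline vertices in
#'   micrometres, ordered along the boundary; the ring is closed implicitly.
#' @param stage Stage value at which the outline was taken.
#' @param regions Optional named list of sub-polygons (e.g. prospective
#'   autopod/zeugopod) contained in the outline.
#' @return An object of class `tissue_outline`.
#' @export
tissue_outline <- function(polygon, stage = NA_real_, regions = list()) {
  ring <- as_ring(polygon)
  if (poly_area(ring) <= 0) {
    abort("outline must enclose positive area", class = "morphodyn_value_error")
  }
  structure(list(polygon = ring, stage = as.numeric(stage), regions = regions),
            class = "tissue_outline")
}

#' @export
print.tissue_outline <- function(x, ...) {
  cat("<tissue_outline> ", nrow(x$polygon), " vertices, area ",
      signif(poly_area(x$polygon), 4), " um^2\n", sep = "")
  invisible(x)
}

#' Vertex ring of an outline
#'
#' @param outline A [tissue_outline()] or a bare n x 2 vertex matrix.
#' @return The n x 2 vertex ring.
#' @export
outline_ring <- function(outline) {
  if (inherits(outline, "tissue_outline")) outline$polygon else as_ring(outline)
}

#' Read / write a tissue outline as a CSV vertex ring
#'
#' The on-disk format is a CSV with columns `stage`, `vertex_index`, `pd_um`,
#' `ap_um`, one row per vertex in ring order.
#'
#' @param path CSV path.
#' @return For `read_outline`, a [tissue_outline()].
#' @export
read_outline <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("stage", "vertex_index", "pd_um", "ap_um")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort(paste0("outline file is missing column(s): ", paste(missing, collapse = ", ")),
          class = "morphodyn_schema_error")
  }
  raw <- raw[order(raw$vertex_index), ]
  tissue_outline(cbind(raw$pd_um, raw$ap_um), stage = raw$stage[1L])
}

#' @rdname read_outline
#' @param outline A [tissue_outline()].
#' @export
write_outline <- function(outline, path) {
  ring <- outline_ring(outline)
  df <- data.frame(stage = if (inherits(outline, "tissue_outline")) outline$stage else NA_real_,
                   vertex_index = seq_len(nrow(ring)),
                   pd_um = ring[, 1L], ap_um = ring[, 2L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble per-interval landmark correspondences
#'
#' Splits the stage range of a grid into consecutive intervals and, for each
#' interval, collects the pairs (position at interval start, position at
#' interval end) of every spot whose measured stage span covers the interval.
#' Positions between an individual's measurement stages are linearly
#' interpolated in stage; extrapolation beyond the measured span is never
#' performed, so spots that do not span an interval are excluded from it.
#'
#' @param spots A spot tibble (see [read_spot_table()]).
#' @param grid A [stage_grid()] whose stages delimit the intervals.
#' @return A tibble of class `interval_data` with one row per retained
#'   (interval, individual, spot): columns `interval`, `stage_start`,
#'   `stage_end`, `individual_id`, `spot_id`, `X_pd`, `X_ap`, `x_pd`, `x_ap`.
#'   Intervals with no spanning spot raise a classed warning
#'   (`morphodyn_empty_interval`) and are listed in the `empty_intervals`
#'   attribute.
#' @export
build_interval_datasets <- function(spots, grid) {
  stopifnot(inherits(grid, "stage_grid"))
  validate_spot_table(spots)
  spots <- dplyr::arrange(spots, .data$individual_id, .data$spot_id, .data$stage)

  bounds <- grid$stages
  k_max <- length(bounds) - 1L

  per_spot <- spots |>
    dplyr::group_by(.data$individual_id, .data$spot_id) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(
      stage_min = min(.data$stage), stage_max = max(.data$stage),
      stages = list(.data$stage), pd = list(.data$pd_um), ap = list(.data$ap_um),
      .groups = "drop"
    )

  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    s0 <- bounds[k]; s1 <- bounds[k + 1L]
    spans <- per_spot$stage_min <= s0 & per_spot$stage_max >= s1
    if (!any(spans)) next
    sub <- per_spot[spans, ]
    X_pd <- mapply(function(s, v) stats::approx(s, v, xout = s0)$y, sub$stages, sub$pd)
    X_ap <- mapply(function(s, v) stats::approx(s, v, xout = s0)$y, sub$stages, sub$ap)
    x_pd <- mapply(function(s, v) stats::approx(s, v, xout = s1)$y, sub$stages, sub$pd)
    x_ap <- mapply(function(s, v) stats::approx(s, v, xout = s1)$y, sub$stages, sub$ap)
    rows[[k]] <- tibble::tibble(
      interval = k, stage_start = s0, stage_end = s1,
      individual_id = sub$individual_id, spot_id = sub$spot_id,
      X_pd = X_pd, X_ap = X_ap, x_pd = x_pd, x_ap = x_ap
    )
  }
  empty <- which(vapply(rows, is.null, logical(1L)))
  if (length(empty) > 0L) {
    warn(paste0("interval(s) with no spanning spots: ", paste(empty, collapse = ", ")),
         class = "morphodyn_empty_interval")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "empty_intervals") <- empty
  attr(out, "stage_grid") <- grid
  class(out) <- c("interval_data", class(out))
  out
}

interval_pair_matrices <- function(interval_data, k) {
  sub <- interval_data[interval_data$interval == k, , drop = FALSE]
  list(X = cbind(sub$X_pd, sub$X_ap), x = cbind(sub$x_pd, sub$x_ap),
       stage_start = sub$stage_start[1L], stage_end = sub$stage_end[1L])
}
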