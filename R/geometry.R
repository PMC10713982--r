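#' @importFrom rlang abort warn .data
NULL

# Polygon helpers. Rings are n x 2 matrices (pd, ap), implicitly closed;
# vertex order may be either orientation, areas are reported unsigned.

as_ring <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L) {
    abort("a polygon ring needs an n x 2 matrix with n >= 3", class = "morphodyn_geometry_error")
  }
  storage.mode(xy) <- "double"
  if (anyNA(xy) || !all(is.finite(xy))) {
    abort("polygon vertices must be finite", class = "morphodyn_geometry_error")
  }
  # drop duplicated closing vertex
  if (isTRUE(all.equal(xy[1L, ], xy[nrow(xy), ], check.attributes = FALSE))) {
    xy <- xy[-nrow(xy), , drop = FALSE]
  }
  unname(xy)
}

poly_area_signed <- function(xy) {
  xy <- as_ring(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(xy) abs(poly_area_signed(xy))

poly_centroid <- function(xy) {
  xy <- as_ring(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    abort("degenerate (zero-area) polygon", class = "morphodyn_geometry_error")
  }
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

points_in_poly <- function(pts, ring, boundary = TRUE) {
  ring <- as_ring(ring)
  pts <- matrix(as.numeric(pts), ncol = 2L)
  inside <- pracma::inpolygon(pts[, 1L], pts[, 2L], ring[, 1L], ring[, 2L],
                              boundary = boundary)
  as.logical(inside)
}

# Resample a ring at M points equally spaced in arc length.
resample_ring <- function(xy, M = 200L) {
  xy <- as_ring(xy)
  closed <- rbind(xy, xy[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) abort("degenerate polygon outline", class = "morphodyn_geometry_error")
  target <- seq(0, total, length.out = M + 1L)[-(M + 1L)]
  cbind(stats::approx(s, closed[, 1L], xout = target)$y,
        stats::approx(s, closed[, 2L], xout = target)$y)
}

# Sutherland-Hodgman clip of a ring against the half-plane {p : <n, p> >= c}.
clip_halfplane <- function(xy, normal, offset) {
  xy <- as_ring(xy)
  n <- nrow(xy)
  d <- as.numeric(xy %*% normal) - offset
  out <- vector("list", 2L * n)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- d[i] >= 0; pj_in <- d[j] >= 0
    if (pi_in) {
      m <- m + 1L; out[[m]] <- xy[i, ]
    }
    if (xor(pi_in, pj_in)) {
      tt <- d[i] / (d[i] - d[j])
      m <- m + 1L; out[[m]] <- xy[i, ] + tt * (xy[j, ] - xy[i, ])
    }
  }
  if (m < 3L) return(NULL)
  do.call(rbind, out[seq_len(m)])
}

# Regular lattice (multiples of `spacing`, anchored at the origin) clipped to a ring.
lattice_in_polygon <- function(ring, spacing, boundary = TRUE) {
  ring <- as_ring(ring)
  rx <- range(ring[, 1L]); ry <- range(ring[, 2L])
  ix <- seq(floor(rx[1L] / spacing), ceiling(rx[2L] / spacing))
  iy <- seq(floor(ry[1L] / spacing), ceiling(ry[2L] / spacing))
  g <- expand.grid(ix = ix, iy = iy)
  pts <- cbind(g$ix * spacing, g$iy * spacing)
  keep <- points_in_poly(pts, ring, boundary = boundary)
  tibble::tibble(ix = g$ix[keep], iy = g$iy[keep],
                 x = pts[keep, 1L], y = pts[keep, 2L])
}

# Quadrature points for area integrals: cell centres of an n x n grid over the
# bounding box. Cells straddling the outline get fractional weights (the
# inside fraction of a 2 x 2 subsample), so area averages converge at second
# order instead of being limited by O(h) boundary-cell error.
quad_points <- function(ring, n_grid = 25L) {
  ring <- as_ring(ring)
  rx <- range(ring[, 1L]); ry <- range(ring[, 2L])
  hx <- diff(rx) / n_grid; hy <- diff(ry) / n_grid
  cx <- rx[1L] + (seq_len(n_grid) - 0.5) * hx
  cy <- ry[1L] + (seq_len(n_grid) - 0.5) * hy
  g <- expand.grid(x = cx, y = cy)
  pts <- cbind(g$x, g$y)
  frac <- rep(0, nrow(pts))
  for (ox in c(-0.25, 0.25)) {
    for (oy in c(-0.25, 0.25)) {
      sub <- cbind(pts[, 1L] + ox * hx, pts[, 2L] + oy * hy)
      frac <- frac + points_in_poly(sub, ring, boundary = FALSE) / 4
    }
  }
  keep <- frac > 0
  if (!any(keep)) {
    abort("quadrature grid too coarse: no points fall inside the outline",
          class = "morphodyn_resolution_error")
  }
  list(points = pts[keep, , drop = FALSE], weights = frac[keep],
       cell_area = hx * hy)
}

#' Intersection-over-union of two polygons
#'
#' Estimated by point-in-polygon counting on an n x n lattice over the joint
#' bounding box; the rasterization error is O(1/n) and negligible at the
#' tolerances used for region-overlap comparisons.
#'
#' @param ring_a,ring_b Vertex rings (n x 2 matrices) or [tissue_outline()]s.
#' @param n Lattice resolution per axis.
#' @return Scalar IoU in [0, 1].
#' @export
polygon_iou <- function(ring_a, ring_b, n = 200L) {
  if (inherits(ring_a, "tissue_outline")) ring_a <- ring_a$polygon
  if (inherits(ring_b, "tissue_outline")) ring_b <- ring_b$polygon
  ring_a <- as_ring(ring_a); ring_b <- as_ring(ring_b)
  rx <- range(ring_a[, 1L], ring_b[, 1L])
  ry <- range(ring_a[, 2L], ring_b[, 2L])
  gx <- seq(rx[1L], rx[2L], length.out = n)
  gy <- seq(ry[1L], ry[2L], length.out = n)
  g <- expand.grid(x = gx, y = gy)
  pts <- cbind(g$x, g$y)
  in_a <- points_in_poly(pts, ring_a)
  in_b <- points_in_poly(pts, ring_b)
  union <- sum(in_a | in_b)
  if (union == 0L) return(0)
  sum(in_a & in_b) / union
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# third-index slice of an n x 2 x S array that never drops to a vector
slice3 <- function(a, s) matrix(a[, , s], ncol = 2L)

# fourth-index slice of a 2 x 2 x n x S array that keeps all three dims
slice4 <- function(a, s) array(a[, , , s], dim = dim(a)[1:3])
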