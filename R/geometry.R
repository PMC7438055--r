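#' Geometry configuration for procedural cell contours
#'
#' Cells are modelled as jittered ellipses: a radius and eccentricity are
#' drawn per cell, the boundary is sampled at `n_vertices` angles and each
#' vertex radius is perturbed by up to `jitter` (fractional). This reproduces
#' the area and overlap statistics of segmented somata without requiring any
#' recorded movie.
#'
#' @param radius_range numeric(2), semi-major axis bounds in pixels.
#' @param max_eccentricity maximum ratio of major to minor axis (>= 1).
#' @param jitter maximal fractional boundary perturbation in [0, 1).
#' @param n_vertices number of polygon vertices.
#' @param nucleus_scale linear scale of the concentric nucleus polygon.
#' @return a list of class `cacti_geometry`.
#' @export
geometry_config <- function(radius_range = c(4, 8), max_eccentricity = 2,
                            jitter = 0.2, n_vertices = 16,
                            nucleus_scale = 0.5) {
  if (any(radius_range <= 0)) stop_config("geometry: radius bounds must be positive")
  if (max_eccentricity < 1) stop_config("geometry: max_eccentricity must be >= 1")
  if (jitter < 0 || jitter >= 1) stop_config("geometry: jitter must be in [0, 1)")
  if (nucleus_scale <= 0 || nucleus_scale >= 1)
    stop_config("geometry: nucleus_scale must be in (0, 1)")
  structure(list(radius_range = radius_range,
                 max_eccentricity = max_eccentricity,
                 jitter = jitter, n_vertices = as.integer(n_vertices),
                 nucleus_scale = nucleus_scale),
            class = "cacti_geometry")
}

# Rasterize a closed polygon (k x 2 matrix of x, y) to pixel centers.
# Returns an integer matrix of (x, y) pixel coordinates (0-based convention
# is the caller's concern; here coordinates are whatever integer lattice the
# polygon spans).
rasterize_polygon <- function(poly) {
  xs <- seq(floor(min(poly[, 1])), ceiling(max(poly[, 1])))
  ys <- seq(floor(min(poly[, 2])), ceiling(max(poly[, 2])))
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                         matrix(as.numeric(grid), ncol = 2))
  grid[inside, , drop = FALSE]
}

# Build one jittered-ellipse contour centered at the origin.
make_contour <- function(cell_id, geom) {
  a <- stats::runif(1, geom$radius_range[1], geom$radius_range[2])
  ecc <- stats::runif(1, 1, geom$max_eccentricity)
  b <- a / ecc
  theta <- stats::runif(1, 0, pi)
  ang <- seq(0, 2 * pi, length.out = geom$n_vertices + 1)[-(geom$n_vertices + 1)]
  ex <- a * cos(ang); ey <- b * sin(ang)
  # rotate by theta
  x <- ex * cos(theta) - ey * sin(theta)
  y <- ex * sin(theta) + ey * cos(theta)
  pert <- 1 + stats::runif(geom$n_vertices, -geom$jitter, geom$jitter)
  poly <- cbind(x * pert, y * pert)
  mask <- rasterize_polygon(poly)
  if (nrow(mask) == 0L) stop_config("contour rasterized to an empty mask")
  nuc_poly <- poly * geom$nucleus_scale
  nuc <- rasterize_polygon(nuc_poly)
  # the nucleus must stay inside the cell mask
  keys <- pixel_key(mask, 4096L)
  nuc <- nuc[pixel_key(nuc, 4096L) %in% keys, , drop = FALSE]
  soma <- mask[!(keys %in% pixel_key(nuc, 4096L)), , drop = FALSE]
  structure(list(cell_id = as.integer(cell_id), polygon = poly,
                 mask = mask, nucleus_mask = nuc, soma_mask = soma),
            class = "cacti_contour")
}

#' Generate a library of procedural cell contours
#'
#' @param n number of contours.
#' @param geometry a [geometry_config()].
#' @param seed integer RNG seed; identical seeds give identical libraries.
#' @return list of `cacti_contour`, each centered at the origin with a
#'   soma/nucleus partition of its mask.
#' @export
generate_contour_library <- function(n, geometry = geometry_config(),
                                     seed = NULL) {
  if (n < 1) stop_config("contour library: n must be >= 1")
  with_seed(seed, lapply(seq_len(n), function(i) make_contour(i, geometry)))
}

# Translate a contour to an integer center (cx, cy).
translate_contour <- function(contour, cx, cy) {
  sh <- function(m) {
    m[, 1] <- m[, 1] + cx; m[, 2] <- m[, 2] + cy; m
  }
  contour$polygon <- sh(contour$polygon)
  contour$mask <- sh(contour$mask)
  contour$nucleus_mask <- sh(contour$nucleus_mask)
  contour$soma_mask <- sh(contour$soma_mask)
  contour$center <- c(cx, cy)
  contour
}

#' @export
print.cacti_contour <- function(x, ...) {
  cat(sprintf("<cacti_contour> cell %d: %d px (%d soma, %d nucleus)\n",
              x$cell_id, nrow(x$mask), nrow(x$soma_mask), nrow(x$nucleus_mask)))
  invisible(x)
}
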