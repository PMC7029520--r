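# Small planar-polygon utilities used by the geometry module. Polygons are
# n x 2 matrices of vertices in mm, implicitly closed (last vertex joins the
# first), counter-clockwise for outer contours.

#' Polygon area (shoelace formula)
#'
#' @param poly An `n x 2` matrix of vertices in mm, implicitly closed.
#' @return Area in mm^2 (non-negative).
#' @export
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Polygon centroid
#'
#' @inheritParams poly_area
#' @return Length-2 numeric vector (x, y) in mm.
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Polygon perimeter
#'
#' @inheritParams poly_area
#' @return Perimeter in mm.
#' @export
poly_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(sqrt((x2 - x)^2 + (y2 - y)^2))
}

#' Test points for inclusion in a polygon
#'
#' Even-odd (ray casting) test.
#'
#' @param x,y Point coordinates (vectors), mm.
#' @inheritParams poly_area
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  cpp_points_in_poly(as.numeric(x), as.numeric(y), poly)
}

#' Distance from points to a polygon boundary
#'
#' @inheritParams points_in_polygon
#' @return Numeric vector of distances (mm) to the nearest polygon edge.
#' @export
distance_to_polygon <- function(x, y, poly) {
  cpp_dist_to_poly(as.numeric(x), as.numeric(y), poly)
}

# Regular polygon approximating an ellipse. By default the radii are
# inflated so the *polygon* area equals pi*a*b exactly; with
# `exact_vertices` the vertices lie exactly on the ellipse instead.
ellipse_polygon <- function(center, a, b, angle = 0, n = 48,
                            exact_vertices = FALSE) {
  corr <- if (exact_vertices) 1 else sqrt(2 * pi / (n * sin(2 * pi / n)))
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  px <- a * corr * cos(t)
  py <- b * corr * sin(t)
  ca <- cos(angle); sa <- sin(angle)
  cbind(center[1] + px * ca - py * sa,
        center[2] + px * sa + py * ca)
}

# Minimum boundary-to-boundary distance between two disjoint convex-ish
# polygons (vertex-to-edge both ways; exact for convex pairs).
poly_min_distance <- function(a, b) {
  min(min(cpp_dist_to_poly(a[, 1], a[, 2], b)),
      min(cpp_dist_to_poly(b[, 1], b[, 2], a)))
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed (< 2^31) from a base seed and a tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}
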