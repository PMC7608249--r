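## Planar polygon primitives used for arena zones.  A polygon is an n x 2
## numeric matrix of vertices in order (not repeated at the end).  A zone is
## either a polygon or a `zone_region` (an outer polygon with holes), which
## represents ring-shaped zones such as the wall band.

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || !is.numeric(poly)) {
    stop_ctx("a polygon is an n x 2 numeric matrix", class = "skeletrack_domain")
  }
  unname(poly)
}

polygon_signed_area <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n < 3L) {
    stop_ctx("polygon needs at least 3 vertices", class = "skeletrack_domain")
  }
  i2 <- c(2:n, 1L)
  sum(poly[, 1L] * poly[i2, 2L] - poly[i2, 1L] * poly[, 2L]) / 2
}

#' Polygon area (shoelace formula)
#' @param poly An n x 2 vertex matrix (n >= 3), vertices in order.
#' @return Absolute enclosed area, in squared input units.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(45, 0), c(45, 45), c(0, 45)))  # 2025
polygon_area <- function(poly) {
  abs(polygon_signed_area(poly))
}

#' Polygon centroid
#' @param poly An n x 2 vertex matrix (n >= 3) with nonzero area.
#' @return Length-2 numeric vector (x, y) of the area centroid.
#' @export
polygon_centroid <- function(poly) {
  poly <- as_polygon(poly)
  a <- polygon_signed_area(poly)
  if (abs(a) < .Machine$double.eps) {
    stop_ctx("degenerate polygon: zero area", class = "skeletrack_domain")
  }
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  cross <- poly[, 1L] * poly[i2, 2L] - poly[i2, 1L] * poly[, 2L]
  c(sum((poly[, 1L] + poly[i2, 1L]) * cross) / (6 * a),
    sum((poly[, 2L] + poly[i2, 2L]) * cross) / (6 * a))
}

#' Shrink a polygon about its centroid to a fraction of its area
#'
#' Scales every vertex toward the area centroid by `sqrt(area_fraction)`,
#' so the result is a similar polygon enclosing exactly `area_fraction`
#' times the original area.  This is the "polygon scaling" used to derive
#' proportional zones, e.g. the central 50% of an open field.
#'
#' @param poly An n x 2 vertex matrix, simple, with positive area.
#' @param area_fraction Target area as a fraction of the input area,
#'   in (0, 1].
#' @return The scaled polygon (same vertex count and order).
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(45, 0), c(45, 45), c(0, 45))
#' polygon_area(scale_polygon(sq, 0.5))  # 1012.5
scale_polygon <- function(poly, area_fraction) {
  if (!is.finite(area_fraction) || area_fraction <= 0 || area_fraction > 1) {
    stop_ctx("area_fraction must lie in (0, 1]", class = "skeletrack_domain")
  }
  poly <- as_polygon(poly)
  ctr <- polygon_centroid(poly)
  k <- sqrt(area_fraction)
  sweep(sweep(poly, 2L, ctr, "-") * k, 2L, ctr, "+")
}

#' Point-in-polygon test
#'
#' Standard even-odd (ray casting) test, vectorized over points; points on
#' a polygon edge or vertex count as inside.  For a [zone_region()] a point
#' is inside when it is inside the outer polygon and in no hole (hole
#' boundaries count as part of the region).
#'
#' @param pts An m x 2 matrix of points (or a length-2 vector).
#' @param zone A polygon matrix or a `zone_region`.
#' @return Logical vector of length m.
#' @export
point_in_zone <- function(pts, zone) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  pts <- as.matrix(pts)
  if (inherits(zone, "zone_region")) {
    inside <- point_in_zone(pts, zone$outer)
    for (h in zone$holes) {
      in_hole <- point_in_polygon_impl(pts, as_polygon(h))
      # interior of a hole is excluded; its boundary belongs to the region
      inside <- inside & !(in_hole$interior & !in_hole$boundary)
    }
    return(inside)
  }
  res <- point_in_polygon_impl(pts, as_polygon(zone))
  res$interior | res$boundary
}

# Even-odd crossing test; returns interior (crossing parity, boundary
# excluded) and boundary (point on an edge) flags.
point_in_polygon_impl <- function(pts, poly) {
  n <- nrow(poly)
  if (n < 3L) {
    stop_ctx("polygon needs at least 3 vertices", class = "skeletrack_domain")
  }
  px <- pts[, 1L]; py <- pts[, 2L]
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    # on-segment check
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    scale <- max(abs(c(xi, yi, xj, yj, 1)))
    boundary <- boundary | (abs(cross) <= 1e-9 * scale^2 & within)
    # ray casting (horizontal ray to +x)
    crosses <- ((yi > py) != (yj > py))
    xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
    flip <- crosses & (px < xint)
    flip[is.na(flip)] <- FALSE
    inside <- xor(inside, flip)
    j <- i
  }
  list(interior = inside, boundary = boundary)
}

#' A ring-shaped zone: an outer polygon minus hole polygons
#' @param outer Outer boundary polygon.
#' @param holes List of hole polygons fully inside `outer`.
#' @return Object of class `zone_region`.
#' @export
zone_region <- function(outer, holes = list()) {
  structure(list(outer = as_polygon(outer),
                 holes = lapply(holes, as_polygon)),
            class = "zone_region")
}

#' Area of a polygon or zone region
#' @param zone Polygon matrix or [zone_region()].
#' @return Area (outer minus holes for a region).
#' @export
zone_area <- function(zone) {
  if (inherits(zone, "zone_region")) {
    polygon_area(zone$outer) - sum(vapply(zone$holes, polygon_area, 0))
  } else {
    polygon_area(zone)
  }
}

# Inward edge offset of a convex polygon: every edge is displaced by
# `dist` along its inward normal and consecutive offset lines are
# intersected.  Exact for convex polygons, which covers the shipped arena
# templates (rectangles, regular polygons approximating circles).
inset_convex_polygon <- function(poly, dist) {
  poly <- as_polygon(poly)
  if (polygon_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  e <- poly[i2, ] - poly                      # edge vectors
  len <- sqrt(rowSums(e^2))
  if (any(len == 0)) {
    stop_ctx("polygon has zero-length edge", class = "skeletrack_domain")
  }
  nrm <- cbind(-e[, 2L], e[, 1L]) / len       # inward normal (CCW orientation)
  p_off <- poly + dist * nrm                  # a point on each offset line
  out <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L           # previous edge
    # intersect offset lines of edges j and i
    A <- rbind(c(e[j, 2L], -e[j, 1L]), c(e[i, 2L], -e[i, 1L]))
    b <- c(e[j, 2L] * p_off[j, 1L] - e[j, 1L] * p_off[j, 2L],
           e[i, 2L] * p_off[i, 1L] - e[i, 1L] * p_off[i, 2L])
    if (abs(det(A)) < 1e-12 * max(1, max(abs(A)))^2) {
      # collinear consecutive edges: drop the redundant vertex
      out[i, ] <- p_off[i, ]
    } else {
      out[i, ] <- solve(A, b)
    }
  }
  if (polygon_signed_area(out) <= 0 ||
      polygon_area(out) >= polygon_area(poly)) {
    stop_ctx("band too wide: inward offset leaves no interior",
             class = "skeletrack_domain")
  }
  # every inset vertex must keep the offset distance from every edge of the
  # original polygon; a violation means the offset exceeded the inradius
  for (v in seq_len(n)) {
    for (ed in seq_len(n)) {
      a <- poly[ed, ]; b <- poly[i2[ed], ]
      ab <- b - a
      t <- max(0, min(1, sum((out[v, ] - a) * ab) / sum(ab^2)))
      if (sqrt(sum((a + t * ab - out[v, ])^2)) < dist * (1 - 1e-9)) {
        stop_ctx("band too wide: inward offset leaves no interior",
                 class = "skeletrack_domain")
      }
    }
  }
  out
}

#' Split an arena into a wall band and an inner zone
#'
#' The inner zone is the arena polygon shrunk inward by a true edge offset
#' of `band_width` (every inner point is at least `band_width` from every
#' wall); the wall zone is the ring between the arena outline and the inner
#' zone.  Used for the supported-rear wall band: rears within the band are
#' within reach of a wall.
#'
#' @param arena Convex arena polygon (calibrated units).
#' @param band_width Band width, same units as the polygon (e.g. 12.5 cm).
#' @return List with `wall_zone` (a [zone_region()]) and `inner_zone`
#'   (a polygon).
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(45, 0), c(45, 45), c(0, 45))
#' zone_area(wall_band_zones(sq, 12.5)$inner_zone)  # 20 x 20 = 400
wall_band_zones <- function(arena, band_width) {
  arena <- as_polygon(arena)
  if (band_width < 0) {
    stop_ctx("band_width must be >= 0", class = "skeletrack_domain")
  }
  if (band_width == 0) {
    return(list(wall_zone = zone_region(arena, holes = list(arena)),
                inner_zone = arena))
  }
  inner <- inset_convex_polygon(arena, band_width)
  list(wall_zone = zone_region(arena, holes = list(inner)),
       inner_zone = inner)
}

# Least-squares circle fit (Kasa method): linear in (a, b, c) with
# x^2 + y^2 = 2 a x + 2 b y + c; radius = sqrt(c + a^2 + b^2).
fit_circle <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) {
    stop_ctx("circle fit needs at least 3 points", class = "skeletrack_domain")
  }
  A <- cbind(2 * pts[, 1L], 2 * pts[, 2L], 1)
  z <- pts[, 1L]^2 + pts[, 2L]^2
  sol <- unname(stats::lm.fit(A, z)$coefficients)
  centre <- sol[1:2]
  r2 <- sol[3L] + sum(centre^2)
  if (!is.finite(r2) || r2 <= 0) {
    stop_ctx("degenerate rim points: circle fit failed",
             class = "skeletrack_domain")
  }
  list(centre = unname(centre), radius = sqrt(r2))
}

# Regular n-gon approximating a circle, used as the FST arena polygon.
circle_polygon <- function(centre, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1L] + radius * cos(th), centre[2L] + radius * sin(th))
}
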