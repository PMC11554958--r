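#' Polygon geometry utilities
#'
#' Minimal planar geometry for simple polygons in a projected (metric)
#' coordinate system. A polygon is a two-column numeric matrix of exterior
#' ring vertices (x, y); the ring may be open or closed, rings with holes are
#' not supported.
#'
#' @name geometry
#' @keywords internal
NULL

# Drop a repeated closing vertex so downstream loops see each vertex once.
ring_open <- function(poly) {
  poly <- as.matrix(poly)
  storage.mode(poly) <- "double"
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

#' Signed and absolute polygon area
#'
#' Shoelace formula. Positive signed area means counter-clockwise vertex
#' order.
#'
#' @param poly two-column matrix of ring vertices.
#' @return area in squared map units (signed for `polygon_area_signed`).
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' @rdname polygon_area
#' @export
polygon_area_signed <- function(poly) {
  p <- ring_open(poly)
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

#' Polygon centroid (area-weighted)
#'
#' @param poly two-column vertex matrix.
#' @return numeric length-2 (x, y).
#' @export
polygon_centroid <- function(poly) {
  p <- ring_open(poly)
  n <- nrow(p)
  if (n < 3) return(colMeans(p))
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

#' Point-in-polygon test
#'
#' Even-odd ray casting, vectorized over query points. Points exactly on an
#' edge are resolved by the half-open convention of the crossing rule; cell
#' centers at half-resolution offsets never coincide with edges of polygons
#' whose vertices lie on cell corners, so rasterization by cell-center
#' containment is exact there.
#'
#' @param px,py coordinates of query points.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  p <- ring_open(poly)
  n <- nrow(p)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Distance from points to segments (a, b); vectorized over points and/or
# segments (recycled as in base arithmetic).
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0,
              pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) /
                             ifelse(len2 > 0, len2, 1))),
              0)
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

segments_of <- function(poly) {
  p <- ring_open(poly)
  n <- nrow(p)
  cbind(p, p[c(2:n, 1), , drop = FALSE])   # ax ay bx by
}

#' Minimum distance from a point to a polygon boundary or interior
#'
#' Zero if the point lies inside the polygon.
#'
#' @param px,py point coordinates (scalars).
#' @param poly two-column vertex matrix.
#' @export
polygon_point_distance <- function(px, py, poly) {
  if (point_in_polygon(px, py, poly)) return(0)
  s <- segments_of(poly)
  min(point_segment_distance(px, py, s[, 1], s[, 2], s[, 3], s[, 4]))
}

#' Minimum distance between two polygons
#'
#' Minimum Euclidean distance between boundaries; zero if one polygon's
#' vertex lies inside the other (overlap beyond vertex containment is not
#' detected, which suffices for the non-overlapping field registries used
#' here).
#'
#' @param a,b two-column vertex matrices.
#' @export
polygon_distance <- function(a, b) {
  pa <- ring_open(a); pb <- ring_open(b)
  if (any(point_in_polygon(pa[, 1], pa[, 2], b))) return(0)
  if (any(point_in_polygon(pb[, 1], pb[, 2], a))) return(0)
  sa <- segments_of(a); sb <- segments_of(b)
  d <- Inf
  for (i in seq_len(nrow(sa))) {
    d <- min(d, min(point_segment_distance(pb[, 1], pb[, 2],
                                           sa[i, 1], sa[i, 2], sa[i, 3], sa[i, 4])))
  }
  for (i in seq_len(nrow(sb))) {
    d <- min(d, min(point_segment_distance(pa[, 1], pa[, 2],
                                           sb[i, 1], sb[i, 2], sb[i, 3], sb[i, 4])))
  }
  d
}

#' Clip a polygon by a convex polygon (Sutherland-Hodgman)
#'
#' @param subject polygon to be clipped (any simple polygon).
#' @param clip convex clip polygon; vertices may be in either orientation.
#' @return clipped polygon vertex matrix, or a 0-row matrix if empty.
#' @export
clip_polygon_convex <- function(subject, clip) {
  clip <- ring_open(clip)
  if (polygon_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- ring_open(subject)
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    input <- out
    if (is.null(input) || nrow(input) == 0) break
    out <- matrix(numeric(0), ncol = 2)
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    isect <- function(p, q) {
      # intersection of segment pq with the infinite clip edge ab
      x1 <- p[1]; y1 <- p[2]; x2 <- q[1]; y2 <- q[2]
      x3 <- a[1]; y3 <- a[2]; x4 <- b[1]; y4 <- b[2]
      den <- (x1 - x2) * (y3 - y4) - (y1 - y2) * (x3 - x4)
      t <- ((x1 - x3) * (y3 - y4) - (y1 - y3) * (x3 - x4)) / den
      c(x1 + t * (x2 - x1), y1 + t * (y2 - y1))
    }
    n <- nrow(input)
    for (i in seq_len(n)) {
      cur <- input[i, ]; prev <- input[if (i == 1) n else i - 1, ]
      cin <- side(cur) >= 0; pin <- side(prev) >= 0
      if (cin) {
        if (!pin) out <- rbind(out, isect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, isect(prev, cur))
      }
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  colnames(out) <- c("x", "y")
  out
}

#' Axis-aligned rectangle polygon
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds in map units.
#' @return two-column vertex matrix (counter-clockwise).
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Convexity test for a simple polygon
#' @param poly two-column vertex matrix.
#' @export
polygon_is_convex <- function(poly) {
  p <- ring_open(poly)
  n <- nrow(p)
  if (n < 4) return(TRUE)
  s <- 0L
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[if (i == n) 1 else i + 1, ]
    d <- p[if (i >= n - 1) i - n + 2 else i + 2, ]
    cr <- (b[1] - a[1]) * (d[2] - b[2]) - (b[2] - a[2]) * (d[1] - b[1])
    if (abs(cr) > 1e-9) {
      sg <- sign(cr)
      if (s == 0L) s <- sg else if (sg != s) return(FALSE)
    }
  }
  TRUE
}
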