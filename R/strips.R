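#' Longest straight edge of a field polygon
#'
#' The longest segment between consecutive exterior-ring vertices; ties are
#' broken by first occurrence in ring order from the ring's first vertex.
#'
#' @param poly two-column vertex matrix.
#' @return 2 x 2 matrix (rows = endpoints a, b).
#' @export
longest_edge <- function(poly) {
  p <- ring_open(poly)
  n <- nrow(p)
  if (n < 3 || polygon_area(p) < 1e-9) stop("degenerate polygon")
  j <- c(2:n, 1)
  len <- sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2)
  k <- which.max(len)   # first occurrence wins ties
  rbind(a = p[k, ], b = p[j[k], ])
}

#' Build a flower strip along a field's longest edge
#'
#' The strip is the longest edge buffered by `width_m` toward the field
#' interior, clipped to the field polygon (exactly for convex fields via
#' Sutherland-Hodgman; non-convex fields keep the unclipped inward
#' rectangle with a warning). The area is recorded from the vector
#' geometry, not from any raster burn.
#'
#' @param poly field polygon.
#' @param field_id id recorded on the strip.
#' @param width_m strip width in m (default 5).
#' @return a `bs_strip` list: `field_id`, `edge`, `polygon`, `area_ha`.
#' @export
build_flower_strip <- function(poly, field_id = NA_integer_, width_m = 5) {
  edge <- longest_edge(poly)
  a <- edge[1, ]; b <- edge[2, ]
  v <- b - a
  len <- sqrt(sum(v^2))
  nrm <- c(-v[2], v[1]) / len
  mid <- (a + b) / 2
  probe <- mid + nrm * min(width_m, len) / 10
  if (!point_in_polygon(probe[1], probe[2], poly)) nrm <- -nrm
  strip <- rbind(a, b, b + width_m * nrm, a + width_m * nrm)
  if (polygon_is_convex(poly)) {
    clipped <- clip_polygon_convex(strip, poly)
    if (nrow(clipped) >= 3) strip <- clipped
  } else {
    warning("non-convex field ", field_id, ": strip not clipped to the field")
  }
  area_ha <- polygon_area(strip) / 1e4
  if (area_ha < 0.1 * width_m * len / 1e4)
    warning("pathological sliver strip on field ", field_id)
  structure(list(field_id = field_id, edge = edge, polygon = strip,
                 area_ha = area_ha),
            class = "bs_strip")
}

# Cells to burn for a strip: cells whose center lies inside the strip
# polygon, plus the field's cells crossed by the strip centerline (5-m
# strips at 30-m cells rarely contain a center, so the boundary row of
# cells along the base edge is used). Restricted to the strip's own field.
strip_cells <- function(strip, grid, labels) {
  cx <- cell_centers_x(grid); cy <- cell_centers_y(grid)
  poly <- strip$polygon
  cols <- which(cx > min(poly[, 1]) - grid$resolution &
                  cx < max(poly[, 1]) + grid$resolution)
  rows <- which(cy > min(poly[, 2]) - grid$resolution &
                  cy < max(poly[, 2]) + grid$resolution)
  hits <- integer(0)
  if (length(cols) && length(rows)) {
    px <- rep(cx[cols], each = length(rows))
    py <- rep(cy[rows], times = length(cols))
    inpoly <- point_in_polygon(px, py, poly)
    rr <- rep(rows, times = length(cols))[inpoly]
    cc <- rep(cols, each = length(rows))[inpoly]
    hits <- (cc - 1L) * grid$n_rows + rr
  }
  # centerline sampling fallback
  a <- strip$edge[1, ]; b <- strip$edge[2, ]
  v <- b - a
  len <- sqrt(sum(v^2))
  nrm <- c(-v[2], v[1]) / len
  mid <- (a + b) / 2 + nrm * 1e-6
  if (!point_in_polygon(mid[1], mid[2], rbind(strip$polygon)))
    nrm <- -nrm
  half <- nrm * min(5, len) / 2
  t <- seq(0, 1, length.out = max(2, ceiling(len / (grid$resolution / 3))))
  sx <- a[1] + t * v[1] + half[1]
  sy <- a[2] + t * v[2] + half[2]
  ci <- cell_index(grid, sx, sy)
  ok <- !is.na(ci$row)
  line_cells <- unique((ci$col[ok] - 1L) * grid$n_rows + ci$row[ok])
  cells <- unique(c(hits, line_cells))
  if (!is.na(strip$field_id)) cells <- cells[labels[cells] == strip$field_id]
  cells
}
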