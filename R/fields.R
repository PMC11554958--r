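#' Crop-field registry
#'
#' Holds the field polygons and the per-year cultivation history that drive
#' abandonment detection and pollination demand. Field polygons must be
#' simple, valid and mutually non-overlapping; the history must cover a
#' contiguous window of years (10 in the reference setup).
#'
#' @param polygons named list of two-column vertex matrices; names are the
#'   field ids (coerced to integer).
#' @param history data.frame with columns `field_id`, `year`, `cultivated`
#'   (logical) and `crop_code` (character, NA when uncultivated).
#' @param abandoned,degraded optional integer vectors of flagged field ids
#'   (normally filled in later by the detection stage).
#' @return an object of class `bs_fields` with element `fields` (a
#'   data.frame of id, centroid, area and flags), `polygons` and `history`.
#' @export
field_registry <- function(polygons, history,
                           abandoned = integer(0), degraded = integer(0)) {
  ids <- as.integer(names(polygons))
  if (anyNA(ids) || anyDuplicated(ids)) stop("polygon names must be unique integer field ids")
  cent <- t(vapply(polygons, polygon_centroid, numeric(2)))
  area <- vapply(polygons, polygon_area, numeric(1)) / 1e4
  history <- as.data.frame(history)
  need <- c("field_id", "year", "cultivated", "crop_code")
  miss <- setdiff(need, names(history))
  if (length(miss)) stop("history lacks columns: ", paste(miss, collapse = ", "))
  yrs <- sort(unique(history$year))
  if (length(yrs) > 1 && !all(diff(yrs) == 1))
    stop("history years must form a contiguous window")
  fields <- data.frame(field_id = ids,
                       centroid_x = cent[, 1], centroid_y = cent[, 2],
                       area_ha = area,
                       abandoned = ids %in% abandoned,
                       degraded = ids %in% degraded)
  structure(list(fields = fields, polygons = polygons, history = history,
                 years = yrs),
            class = "bs_fields")
}

#' @export
print.bs_fields <- function(x, ...) {
  cat(sprintf("<bs_fields> %d fields, %.0f ha; history %d-%d; %d abandoned, %d degraded flagged\n",
              nrow(x$fields), sum(x$fields$area_ha),
              min(x$years), max(x$years),
              sum(x$fields$abandoned), sum(x$fields$degraded)))
  invisible(x)
}

#' Update abandonment/degradation flags on a registry
#'
#' @param registry a `bs_fields`.
#' @param abandoned,degraded integer id vectors; NULL leaves a flag set as is.
#' @export
set_marginal_flags <- function(registry, abandoned = NULL, degraded = NULL) {
  if (!is.null(abandoned))
    registry$fields$abandoned <- registry$fields$field_id %in% abandoned
  if (!is.null(degraded))
    registry$fields$degraded <- registry$fields$field_id %in% degraded
  registry
}

marginal_ids <- function(registry)
  registry$fields$field_id[registry$fields$abandoned | registry$fields$degraded]

#' Rasterize a field registry to an integer label raster
#'
#' Cell membership is decided by cell-center containment: a cell is labelled
#' with the id of the field polygon containing its center, 0 otherwise.
#' Because registries hold non-overlapping polygons the labelling is
#' unambiguous and deterministic.
#'
#' @param registry a [field_registry()].
#' @param grid a [landscape_grid()].
#' @return integer matrix of field ids (0 = no field).
#' @export
rasterize_fields <- function(registry, grid) {
  labels <- new_raster(grid, 0L)
  if (!length(registry$polygons)) return(labels)
  cx <- cell_centers_x(grid); cy <- cell_centers_y(grid)
  xmin <- grid$origin_x; xmax <- grid$origin_x + grid$n_cols * grid$resolution
  ymax <- grid$origin_y; ymin <- grid$origin_y - grid$n_rows * grid$resolution
  for (id in names(registry$polygons)) {
    poly <- ring_open(registry$polygons[[id]])
    if (min(poly[, 1]) < xmin - 1e-9 || max(poly[, 1]) > xmax + 1e-9 ||
        min(poly[, 2]) < ymin - 1e-9 || max(poly[, 2]) > ymax + 1e-9)
      stop("field ", id, " lies outside the grid bounds")
    cols <- which(cx > min(poly[, 1]) & cx < max(poly[, 1]))
    rows <- which(cy > min(poly[, 2]) & cy < max(poly[, 2]))
    if (!length(cols) || !length(rows)) next
    px <- rep(cx[cols], each = length(rows))
    py <- rep(cy[rows], times = length(cols))
    hit <- point_in_polygon(px, py, poly)
    if (any(hit)) {
      rr <- rep(rows, times = length(cols))[hit]
      cc <- rep(cols, each = length(rows))[hit]
      labels[cbind(rr, cc)] <- as.integer(id)
    }
  }
  labels
}
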