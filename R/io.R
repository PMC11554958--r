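#' File I/O for grids, maps and registries
#'
#' All formats are plain text: rasters as ESRI ASCII grids (.asc), class and
#' history tables as CSV, field polygons as GeoJSON. Round-trips preserve
#' codes, class flags and geometry to coordinate precision.
#'
#' @name beescape-io
NULL

#' Write / read a raster as an ESRI ASCII grid
#'
#' @param x numeric or integer matrix (row 1 = northernmost row).
#' @param grid the [landscape_grid()] the raster lives on.
#' @param path file path (.asc).
#' @param digits significant digits used when writing numeric rasters.
#' @export
write_ascii_grid <- function(x, grid, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  yll <- grid$origin_y - grid$n_rows * grid$resolution
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.6f", grid$origin_x),
               sprintf("yllcorner %.6f", yll),
               sprintf("cellsize %.6f", grid$resolution),
               "NODATA_value -9999"), con)
  vals <- x
  vals[is.na(vals)] <- -9999
  for (r in seq_len(grid$n_rows))
    writeLines(paste(format(vals[r, ], digits = digits, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid` returns a list with elements `grid` and
#'   `values` (matrix, NA where NODATA).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  grid <- landscape_grid(nr, nc, resolution = hdr$cellsize,
                         origin_x = hdr$xllcorner,
                         origin_y = hdr$yllcorner + nr * hdr$cellsize)
  list(grid = grid, values = m)
}

#' Write / read a LULC map (ASCII grid + class-table CSV)
#'
#' @param lulc a `bs_lulc`.
#' @param path_raster .asc path for the codes; `path_classes` CSV path for
#'   the class table.
#' @param path_classes,buffer_m see above; `buffer_m` is restored from the
#'   argument on read (it is not encoded in the .asc header).
#' @export
write_lulc <- function(lulc, path_raster, path_classes) {
  write_ascii_grid(lulc$codes, lulc$grid, path_raster, digits = 12)
  utils::write.csv(lulc$class_table, path_classes, row.names = FALSE)
  invisible(path_raster)
}

#' @rdname write_lulc
#' @export
read_lulc <- function(path_raster, path_classes, buffer_m = 2000) {
  ras <- read_ascii_grid(path_raster)
  tab <- utils::read.csv(path_classes, stringsAsFactors = FALSE)
  lulc_map(ras$grid, ras$values, tab, buffer_m = buffer_m)
}

#' Write / read a field registry (GeoJSON polygons + history CSV)
#'
#' @param registry a [field_registry()].
#' @param path_geojson GeoJSON FeatureCollection of field polygons.
#' @param path_history CSV of (field_id, year, cultivated, crop_code).
#' @export
write_registry <- function(registry, path_geojson, path_history) {
  feats <- lapply(seq_len(nrow(registry$fields)), function(i) {
    id <- registry$fields$field_id[i]
    poly <- ring_open(registry$polygons[[as.character(id)]])
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(field_id = id,
                           area_ha = registry$fields$area_ha[i],
                           abandoned = registry$fields$abandoned[i],
                           degraded = registry$fields$degraded[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path_geojson, auto_unbox = TRUE, digits = NA)
  utils::write.csv(registry$history, path_history, row.names = FALSE)
  invisible(path_geojson)
}

#' @rdname write_registry
#' @export
read_registry <- function(path_geojson, path_history) {
  fc <- jsonlite::read_json(path_geojson)
  polys <- list()
  abandoned <- integer(0); degraded <- integer(0)
  for (ft in fc$features) {
    id <- as.integer(ft$properties$field_id)
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]], unlist))
    colnames(ring) <- c("x", "y")
    polys[[as.character(id)]] <- ring_open(ring)
    if (isTRUE(ft$properties$abandoned)) abandoned <- c(abandoned, id)
    if (isTRUE(ft$properties$degraded)) degraded <- c(degraded, id)
  }
  hist <- utils::read.csv(path_history, stringsAsFactors = FALSE)
  hist$cultivated <- as.logical(hist$cultivated)
  field_registry(polys, hist, abandoned = abandoned, degraded = degraded)
}

#' Write / read an annual NDVI stack
#'
#' One ASCII grid per year plus a manifest CSV mapping year to file.
#'
#' @param ndvi 3-d array (rows, cols, years).
#' @param grid the stack's grid.
#' @param years integer vector of years (length = 3rd dim).
#' @param dir output directory; `manifest` CSV written inside it.
#' @export
write_ndvi_stack <- function(ndvi, grid, years, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("ndvi_%d.asc", years)
  for (k in seq_along(years))
    write_ascii_grid(ndvi[, , k], grid, file.path(dir, files[k]), digits = 6)
  utils::write.csv(data.frame(year = years, file = files),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_ndvi_stack
#' @export
read_ndvi_stack <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  first <- read_ascii_grid(file.path(dir, man$file[1]))
  arr <- array(NA_real_, c(first$grid$n_rows, first$grid$n_cols, nrow(man)))
  arr[, , 1] <- first$values
  for (k in seq_len(nrow(man))[-1])
    arr[, , k] <- read_ascii_grid(file.path(dir, man$file[k]))$values
  list(grid = first$grid, years = man$year, values = arr)
}
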