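#' Land-use / land-cover map
#'
#' Couples an integer code raster with a class table carrying the semantics
#' every downstream stage needs: natural / agricultural / cultivated flags
#' and per-class nesting and floral suitabilities on the ordinal scale
#' {0, 0.25, 0.5, 0.75, 1}. Maps carry an analysis buffer: a ring of cells
#' along the border (default 2 km wide) that takes part in kernel and focal
#' computations but is excluded from every reported area or cell statistic,
#' so that foraging bees "see" habitat beyond the territory edge.
#'
#' @param grid a [landscape_grid()].
#' @param codes integer matrix of class codes, dimensions matching `grid`.
#' @param class_table a class table, see [lulc_class_table()].
#' @param buffer_m width in meters of the border ring excluded from
#'   reported statistics (default 2000). Rounded up to whole cells.
#' @return an object of class `bs_lulc`.
#' @export
lulc_map <- function(grid, codes, class_table, buffer_m = 2000) {
  class_table <- lulc_class_table(class_table)
  codes <- matrix(as.integer(codes), nrow = grid$n_rows, ncol = grid$n_cols)
  unknown <- setdiff(unique(as.vector(codes)), class_table$class_id)
  if (length(unknown))
    stop("codes not present in class table: ", paste(unknown, collapse = ", "))
  buffer_cells <- as.integer(ceiling(buffer_m / grid$resolution))
  if (2 * buffer_cells >= min(grid$n_rows, grid$n_cols))
    stop("analysis buffer wider than the grid")
  structure(list(grid = grid, codes = codes, class_table = class_table,
                 buffer_m = buffer_m, buffer_cells = buffer_cells),
            class = "bs_lulc")
}

#' @export
print.bs_lulc <- function(x, ...) {
  print(x$grid)
  tab <- table(factor(as.vector(x$codes), levels = x$class_table$class_id))
  cat(sprintf("  %d classes; buffer %g m (%d cells); core %.0f ha\n",
              nrow(x$class_table), x$buffer_m, x$buffer_cells,
              sum(core_mask(x)) * cell_area_ha(x$grid)))
  nm <- x$class_table$name[match(names(tab), as.character(x$class_table$class_id))]
  cat("  cover:", paste(sprintf("%s=%d", nm[tab > 0], tab[tab > 0]), collapse = " "), "\n")
  invisible(x)
}

#' Validate a LULC class table
#'
#' Required columns: `class_id`, `name`, `is_natural`, `is_agricultural`,
#' `is_cultivated`, at least one `nest_<substrate>` column and one
#' `floral_<season>` column. Suitability values must lie on the scale
#' {0, 0.25, 0.5, 0.75, 1}. A flower-strip class (name containing
#' "flower_strip") must be present even when it has zero extent, so that
#' restoration scenarios never have to invent class codes.
#'
#' @param tab data.frame to validate.
#' @return the validated data.frame (invisibly coerced types).
#' @export
lulc_class_table <- function(tab) {
  need <- c("class_id", "name", "is_natural", "is_agricultural", "is_cultivated")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("class table lacks columns: ", paste(miss, collapse = ", "))
  suit <- grep("^(nest|floral)_", names(tab), value = TRUE)
  if (!any(startsWith(suit, "nest_")) || !any(startsWith(suit, "floral_")))
    stop("class table needs nest_<substrate> and floral_<season> columns")
  tab$class_id <- as.integer(tab$class_id)
  if (anyDuplicated(tab$class_id)) stop("duplicate class_id in class table")
  for (cl in c("is_natural", "is_agricultural", "is_cultivated"))
    tab[[cl]] <- as.logical(tab[[cl]])
  for (cl in suit) {
    v <- tab[[cl]]
    if (!all(v %in% c(0, 0.25, 0.5, 0.75, 1)))
      stop("suitability values in ", cl, " must be in {0, 0.25, 0.5, 0.75, 1}")
  }
  if (!any(grepl("flower_strip", tab$name)))
    stop("class table must include a flower_strip class (zero extent is fine)")
  as.data.frame(tab)
}

#' Packaged land-cover class table
#'
#' Illustrative class table for a southern-Quebec-style intensive
#' agricultural landscape: corn/soy-type row crops, floral crops,
#' non-cultivated agricultural elements, mixed-deciduous forest, wetland,
#' old field / shrubland, urban vegetation, impervious surface, water, bare
#' ground, and a flower-strip class (zero extent at baseline). Suitability
#' entries are relative, literature-style values on {0, 0.25, 0.5, 0.75, 1};
#' any table with the required columns can replace it.
#'
#' @return a class table data.frame.
#' @export
default_class_table <- function() {
  path <- system.file("extdata", "lulc_classes.csv", package = "beescape")
  lulc_class_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

class_row <- function(lulc, what) {
  # per-cell lookup of a class-table column; returns a matrix
  idx <- match(as.vector(lulc$codes), lulc$class_table$class_id)
  matrix(lulc$class_table[[what]][idx], nrow = lulc$grid$n_rows)
}

class_id_by_name <- function(lulc, pattern) {
  hit <- grep(pattern, lulc$class_table$name)
  if (!length(hit)) stop("no class matching '", pattern, "' in class table")
  lulc$class_table$class_id[hit[1]]
}

#' Core (non-buffer) region mask
#'
#' @param lulc a `bs_lulc`.
#' @return logical matrix, TRUE where a cell belongs to the reported
#'   territory (i.e. lies outside the analysis buffer ring).
#' @export
core_mask <- function(lulc) {
  g <- lulc$grid; b <- lulc$buffer_cells
  m <- new_raster(g, FALSE)
  m[(b + 1):(g$n_rows - b), (b + 1):(g$n_cols - b)] <- TRUE
  m
}

#' Territory area in hectares (buffer excluded)
#' @param lulc a `bs_lulc`.
#' @export
territory_ha <- function(lulc) sum(core_mask(lulc)) * cell_area_ha(lulc$grid)

#' Binary natural-habitat mask
#'
#' Natural habitat comprises every class flagged `is_natural` in the class
#' table — forests, wetlands, old fields and shrublands, and flower strips.
#'
#' @param lulc a `bs_lulc`.
#' @return 0/1 matrix on the map's grid.
#' @export
natural_mask <- function(lulc) {
  m <- class_row(lulc, "is_natural")
  mode(m) <- "numeric"
  m
}

#' Reclassify cells of a LULC map
#'
#' Returns a new map in which the selected cells take `class_id`; all other
#' cells and the class table are untouched. This is the primitive every
#' restoration scenario is built from.
#'
#' @param lulc a `bs_lulc`.
#' @param cells cell selector: a logical matrix on the map grid, or an
#'   integer vector of cell indices (column-major).
#' @param class_id target class code, which must exist in the class table.
#' @return a new `bs_lulc`.
#' @export
reclassify <- function(lulc, cells, class_id) {
  class_id <- as.integer(class_id)
  if (!class_id %in% lulc$class_table$class_id)
    stop("unknown class_id: ", class_id)
  codes <- lulc$codes
  if (is.matrix(cells)) {
    stopifnot(identical(dim(cells), dim(codes)))
    codes[cells] <- class_id
  } else if (length(cells)) {
    codes[as.integer(cells)] <- class_id
  }
  out <- lulc
  out$codes <- codes
  out
}

#' Agricultural-zone mask
#'
#' @param lulc a `bs_lulc`.
#' @param labels optional field-label raster from [rasterize_fields()]; when
#'   given, the agricultural zone is taken from the field registry (the
#'   authoritative source for cultivated extent) rather than from the LULC
#'   classes.
#' @return logical matrix.
#' @export
agricultural_mask <- function(lulc, labels = NULL) {
  if (!is.null(labels)) return(labels > 0)
  class_row(lulc, "is_agricultural")
}
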