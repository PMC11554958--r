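#' Crop pollination-dependency table
#'
#' Klein-style dependency classes with numeric weights. The packaged
#' defaults use class midpoints (essential 0.95, great 0.65, modest 0.25,
#' little 0.05, none 0); the table is data and can be overridden, and the
#' headline supply/demand metrics are insensitive to affine changes of
#' these weights because demand is min-max normalized downstream.
#'
#' @param tab data.frame with columns `crop_code`, `dependency_class`,
#'   `weight`.
#' @return validated data.frame.
#' @export
dependency_table <- function(tab) {
  tab <- as.data.frame(tab)
  need <- c("crop_code", "dependency_class", "weight")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("dependency table lacks columns: ", paste(miss, collapse = ", "))
  if (any(tab$weight < 0 | tab$weight > 1)) stop("weights must lie in [0, 1]")
  cls <- c(essential = 5, great = 4, modest = 3, little = 2, none = 1)
  if (!all(tab$dependency_class %in% names(cls)))
    stop("dependency_class must be one of ", paste(names(cls), collapse = ", "))
  # class -> weight must be monotone with none = 0
  agg <- tapply(tab$weight, tab$dependency_class, unique)
  if (any(lengths(agg) > 1)) stop("each dependency class must map to one weight")
  w <- unlist(agg)[names(cls)[names(cls) %in% names(unlist(agg))]]
  ord <- cls[names(w)]
  if (any(diff(w[order(ord)]) < 0)) stop("class weights must increase with dependency")
  if (!is.na(w["none"]) && w["none"] != 0) stop("class 'none' must have weight 0")
  tab
}

#' Packaged dependency table
#' @return validated data.frame matching [default_crop_mix()] crop codes.
#' @export
default_dependency_table <- function() {
  path <- system.file("extdata", "crop_dependency.csv", package = "beescape")
  dependency_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Pollination-dependency weight of crops
#'
#' @param crop_code character vector of crop codes; NA (uncultivated year)
#'   gets weight 0.
#' @param table a [dependency_table()].
#' @return numeric weights in [0, 1].
#' @export
dependency_weight <- function(crop_code, table = default_dependency_table()) {
  idx <- match(crop_code, table$crop_code)
  bad <- !is.na(crop_code) & is.na(idx)
  if (any(bad))
    stop("unknown crop codes: ", paste(unique(crop_code[bad]), collapse = ", "))
  w <- table$weight[idx]
  w[is.na(crop_code)] <- 0
  w
}

#' Mean annual dependency weight of one field over its history
#'
#' Uncultivated (fallow) years contribute weight 0: a field demands no
#' pollination in a year it grows nothing.
#'
#' @param history_field history rows of one field (year, cultivated,
#'   crop_code).
#' @param table dependency table.
#' @return scalar mean weight in [0, 1].
#' @keywords internal
mean_annual_weight <- function(history_field, table) {
  w <- dependency_weight(history_field$crop_code, table)
  w[!history_field$cultivated] <- 0
  mean(w)
}

#' Pollination demand of one field
#'
#' `demand = area_ha * mean over history years of weight(main crop)`;
#' zero when the field is flagged abandoned or degraded (marginal fields
#' have no crop needing pollinators).
#'
#' @param field one row of `registry$fields` (needs `area_ha`, flags).
#' @param history_field that field's history rows.
#' @param table dependency table.
#' @return demand in dependency-weighted hectares (>= 0).
#' @export
field_demand <- function(field, history_field, table = default_dependency_table()) {
  if (isTRUE(field$abandoned) || isTRUE(field$degraded)) return(0)
  field$area_ha * mean_annual_weight(history_field, table)
}

#' Dependency-weighted demand map
#'
#' Computes every field's 10-year mean demand and rasterizes it so that
#' cell values carry area (cell value = field mean annual weight x cell
#' area in ha): summing a field's cells recovers its demand up to
#' rasterization error.
#'
#' @param registry a [field_registry()] with marginal flags set.
#' @param grid the analysis grid.
#' @param table dependency table.
#' @param labels optional precomputed field-label raster.
#' @param core optional logical core mask used for the normalization record.
#' @return a `bs_demand` list: `fields` (field_id, area_ha, mean_weight,
#'   demand), `raster`, `normalized`, `norm_record`.
#' @export
demand_map <- function(registry, grid, table = default_dependency_table(),
                       labels = NULL, core = NULL) {
  if (is.null(labels)) labels <- rasterize_fields(registry, grid)
  fa <- registry$fields
  h <- split(registry$history, registry$history$field_id)
  mw <- vapply(as.character(fa$field_id), function(id)
    mean_annual_weight(h[[id]], table), numeric(1))
  mw[fa$abandoned | fa$degraded] <- 0
  demand <- fa$area_ha * mw
  ras <- new_raster(grid, 0)
  pos <- which(labels > 0)
  idx <- match(labels[pos], fa$field_id)
  ras[pos] <- mw[idx] * cell_area_ha(grid)
  if (is.null(core)) core <- matrix(TRUE, grid$n_rows, grid$n_cols)
  rng <- range(ras[core])
  structure(list(fields = data.frame(field_id = fa$field_id,
                                     area_ha = fa$area_ha,
                                     mean_weight = as.numeric(mw),
                                     demand = as.numeric(demand)),
                 raster = ras,
                 normalized = minmax_scale(ras, core),
                 norm_record = list(min = rng[1], max = rng[2])),
            class = "bs_demand")
}

#' @export
print.bs_demand <- function(x, ...) {
  cat(sprintf("<bs_demand> %d fields, total demand %.1f ha-weighted (%d with demand > 0)\n",
              nrow(x$fields), sum(x$fields$demand), sum(x$fields$demand > 0)))
  invisible(x)
}
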