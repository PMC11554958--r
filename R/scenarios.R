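#' Restoration scenarios
#'
#' Each scenario is a LULC transformation plus a vector-accounted ledger of
#' restored hectares. Raster burns (forest cells, strip cells) feed the
#' supply model; all reported areas come from the vector geometry, since a
#' 5-m strip cannot be represented faithfully by 30-m cells.
#'
#' @name scenarios
NULL

new_scenario <- function(name, lulc, reforested_ha = 0, strips_ha = 0,
                         strips = list(), reforested_ids = integer(0)) {
  terr <- territory_ha(lulc)
  structure(list(name = name, lulc = lulc,
                 ledger = list(reforested_ha = reforested_ha,
                               strips_ha = strips_ha,
                               restored_ha = reforested_ha + strips_ha),
                 restored_fraction = (reforested_ha + strips_ha) / terr,
                 territory_ha = terr,
                 strips = strips, reforested_ids = reforested_ids),
            class = "bs_scenario")
}

#' @export
print.bs_scenario <- function(x, ...) {
  cat(sprintf("<bs_scenario> %s: %.1f ha reforested + %.1f ha strips = %.2f%% of territory\n",
              x$name, x$ledger$reforested_ha, x$ledger$strips_ha,
              100 * x$restored_fraction))
  invisible(x)
}

#' Baseline scenario (no intervention)
#'
#' @param lulc baseline `bs_lulc`.
#' @return a `bs_scenario` with an empty ledger and an identical map.
#' @export
scenario_no_restoration <- function(lulc)
  new_scenario("no_restoration", lulc)

reforest_fields <- function(lulc, labels, ids) {
  if (!length(ids)) return(lulc)
  reclassify(lulc, matrix(labels %in% ids, nrow(labels)),
             class_id_by_name(lulc, "^forest"))
}

burn_strips <- function(lulc, labels, strips) {
  cells <- unlist(lapply(strips, strip_cells, grid = lulc$grid, labels = labels))
  reclassify(lulc, unique(cells), class_id_by_name(lulc, "flower_strip"))
}

#' Scenario: reforestation of abandoned and degraded fields
#'
#' Every cell of every marginal (abandoned or degraded) field becomes
#' forest; the ledger records the vector sum of the member field areas.
#'
#' @param lulc baseline map.
#' @param registry field registry.
#' @param report a [marginal_report()].
#' @param labels field-label raster.
#' @return a `bs_scenario`.
#' @export
scenario_reforest_marginal <- function(lulc, registry, report,
                                       labels = rasterize_fields(registry, lulc$grid)) {
  ids <- report$marginal_ids
  new_scenario("reforest_marginal",
               reforest_fields(lulc, labels, ids),
               reforested_ha = report$total_marginal_ha,
               reforested_ids = ids)
}

build_all_strips <- function(registry, exclude_ids = integer(0), width_m = 5) {
  ids <- setdiff(registry$fields$field_id, exclude_ids)
  lapply(ids, function(id)
    build_flower_strip(registry$polygons[[as.character(id)]],
                       field_id = id, width_m = width_m))
}

#' Scenario: flower strips on field edges
#'
#' A `width_m`-wide flower strip along the longest edge of every crop field
#' except those identified as abandoned or degraded.
#'
#' @inheritParams scenario_reforest_marginal
#' @param width_m strip width in m (default 5).
#' @return a `bs_scenario`.
#' @export
scenario_flower_strips <- function(lulc, registry, report,
                                   labels = rasterize_fields(registry, lulc$grid),
                                   width_m = 5) {
  strips <- build_all_strips(registry, exclude_ids = report$marginal_ids,
                             width_m = width_m)
  new_scenario("flower_strips",
               burn_strips(lulc, labels, strips),
               strips_ha = sum(vapply(strips, `[[`, numeric(1), "area_ha")),
               strips = strips)
}

#' Scenario: mixed strategy with an area cap
#'
#' Prioritization: (1) priority fields are baseline demand hotspots with
#' mean natural cover within 1 km below `cover_max_pct`; (2) candidates are
#' the marginal fields and potential strips intersecting the union of 1-km
#' buffers around priority-field centroids; (3) candidate marginal fields
#' are all reforested; (4) candidate strips are dropped one at a time in
#' ascending order of distance to the nearest marginal field (strips beside
#' future forest are redundant) until the restored total fits
#' `target_fraction` of the territory.
#'
#' @inheritParams scenario_flower_strips
#' @param hotspot_ids field ids of baseline pollination-demand hotspots
#'   (from [bivariate_matrix()]).
#' @param field_cover named numeric vector: mean % natural cover within
#'   `radius_m` of each field centroid (names = field ids).
#' @param target_fraction restored-area cap as a fraction of the territory
#'   (default 0.03).
#' @param radius_m priority-buffer radius in m (default 1000).
#' @param cover_max_pct natural-cover ceiling for priority fields
#'   (default 5).
#' @return a `bs_scenario`.
#' @export
scenario_mixed <- function(lulc, registry, report, hotspot_ids, field_cover,
                           labels = rasterize_fields(registry, lulc$grid),
                           target_fraction = 0.03, radius_m = 1000,
                           cover_max_pct = 5, width_m = 5) {
  terr <- territory_ha(lulc)
  target_ha <- target_fraction * terr
  priority <- intersect(hotspot_ids,
                        as.integer(names(field_cover))[field_cover < cover_max_pct])
  if (!length(priority)) {
    warning("no priority fields: mixed scenario is the identity")
    sc <- new_scenario("mixed", lulc)
    return(sc)
  }
  fa <- registry$fields
  pc <- fa[fa$field_id %in% priority, c("centroid_x", "centroid_y")]
  near_buffers <- function(poly) {
    for (i in seq_len(nrow(pc)))
      if (polygon_point_distance(pc$centroid_x[i], pc$centroid_y[i], poly) <= radius_m)
        return(TRUE)
    FALSE
  }
  cand_marg <- report$marginal_ids[vapply(report$marginal_ids, function(id)
    near_buffers(registry$polygons[[as.character(id)]]), logical(1))]
  strips <- build_all_strips(registry, exclude_ids = report$marginal_ids,
                             width_m = width_m)
  strips <- strips[vapply(strips, function(s) near_buffers(s$polygon), logical(1))]

  reforested_ha <- sum(fa$area_ha[fa$field_id %in% cand_marg])
  marg_polys <- lapply(as.character(report$marginal_ids),
                       function(id) registry$polygons[[id]])
  dist_to_marg <- vapply(strips, function(s) {
    if (!length(marg_polys)) return(Inf)
    min(vapply(marg_polys, polygon_distance, numeric(1), b = s$polygon))
  }, numeric(1))
  ord <- order(dist_to_marg)   # closest to future forest dropped first
  strips <- strips[ord]
  areas <- vapply(strips, `[[`, numeric(1), "area_ha")
  total <- reforested_ha + sum(areas)
  while (length(strips) && total > target_ha) {
    total <- total - strips[[1]]$area_ha
    strips <- strips[-1]
    areas <- areas[-1]
  }
  if (reforested_ha > target_ha)
    warning("reforested area alone exceeds the target; all strips removed")
  out <- reforest_fields(lulc, labels, cand_marg)
  out <- burn_strips(out, labels, strips)
  new_scenario("mixed", out,
               reforested_ha = reforested_ha,
               strips_ha = sum(areas),
               strips = strips, reforested_ids = cand_marg)
}

#' Scenario: maximal restoration
#'
#' All marginal fields reforested, and a flower strip on every other crop
#' field lying strictly farther than `exclusion_m` from every marginal
#' field.
#'
#' @inheritParams scenario_flower_strips
#' @param exclusion_m strip exclusion distance around marginal fields
#'   (default 50).
#' @return a `bs_scenario`.
#' @export
scenario_maximal <- function(lulc, registry, report,
                             labels = rasterize_fields(registry, lulc$grid),
                             exclusion_m = 50, width_m = 5) {
  marg <- report$marginal_ids
  marg_polys <- lapply(as.character(marg), function(id) registry$polygons[[id]])
  keep <- setdiff(registry$fields$field_id, marg)
  if (length(marg)) {
    keep <- keep[vapply(keep, function(id) {
      poly <- registry$polygons[[as.character(id)]]
      all(vapply(marg_polys, polygon_distance, numeric(1), b = poly) > exclusion_m)
    }, logical(1))]
  }
  strips <- lapply(keep, function(id)
    build_flower_strip(registry$polygons[[as.character(id)]],
                       field_id = id, width_m = width_m))
  out <- reforest_fields(lulc, labels, marg)
  out <- burn_strips(out, labels, strips)
  new_scenario("maximal", out,
               reforested_ha = report$total_marginal_ha,
               strips_ha = sum(vapply(strips, `[[`, numeric(1), "area_ha")),
               strips = strips, reforested_ids = marg)
}
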