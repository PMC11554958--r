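#' Min-max scale a raster over a region
#'
#' `(v - min) / (max - min)` with min/max taken over the region mask (the
#' non-buffer territory in normal use). A constant raster maps to all
#' zeros.
#'
#' @param x numeric matrix.
#' @param region logical matrix (default: everything).
#' @return matrix scaled so the region spans [0, 1].
#' @export
minmax_scale <- function(x, region = NULL) {
  if (is.null(region)) region <- matrix(TRUE, nrow(x), ncol(x))
  if (!any(region)) stop("empty region mask")
  rng <- range(x[region])
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

#' Tertile classification
#'
#' Breakpoints at the 1/3 and 2/3 sample quantiles (linear-interpolation
#' convention, `stats::quantile` type 7); `v <= q1` is low, `v <= q2`
#' intermediate, else high.
#'
#' @param values numeric vector (>= 3 values).
#' @return factor with levels low/intermediate/high.
#' @export
tertile_classify <- function(values) {
  if (length(values) < 3) stop("tertile classification needs >= 3 values")
  if (length(unique(values)) < 3)
    warning("fewer than 3 distinct values; tertiles degenerate")
  q <- stats::quantile(values, c(1, 2) / 3, type = 7, names = FALSE)
  cls <- ifelse(values <= q[1], "low",
                ifelse(values <= q[2], "intermediate", "high"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' Bivariate supply-demand classification and demand hotspots
#'
#' Tertiles are computed independently for per-field supply and demand
#' (rank-based, so any strictly monotone transform of either axis leaves
#' the result unchanged); the 3 x 3 matrix holds the % of cultivated area
#' in each combination. Hotspots for pollination demand are fields with
#' intermediate-to-high demand and low supply.
#'
#' @param supply per-field supply values.
#' @param demand per-field demand values.
#' @param area_ha per-field areas.
#' @param field_id per-field ids.
#' @return a `bs_bivariate` list: `fields` (id, tertiles), `matrix`
#'   (supply x demand, % of area, rows = supply low..high), `hotspot_ids`,
#'   `hotspot_pct` (% of cultivated area in hotspots).
#' @export
bivariate_matrix <- function(supply, demand, area_ha, field_id = seq_along(supply)) {
  stopifnot(length(supply) == length(demand), length(demand) == length(area_ha))
  st <- tertile_classify(supply)
  dt <- tertile_classify(demand)
  m <- matrix(0, 3, 3, dimnames = list(supply = levels(st), demand = levels(dt)))
  agg <- tapply(area_ha, list(st, dt), sum, default = 0)
  m[rownames(agg), colnames(agg)] <- agg
  m <- 100 * m / sum(area_ha)
  hot <- st == "low" & dt %in% c("intermediate", "high")
  structure(list(fields = data.frame(field_id = field_id,
                                     supply_tertile = st, demand_tertile = dt),
                 matrix = m,
                 hotspot_ids = field_id[hot],
                 hotspot_pct = sum(m["low", c("intermediate", "high")])),
            class = "bs_bivariate")
}

#' @export
print.bs_bivariate <- function(x, ...) {
  cat("<bs_bivariate> % of cultivated area (rows = supply tertile):\n")
  print(round(x$matrix, 1))
  cat(sprintf("  hotspots: %d fields, %.1f%% of area\n",
              length(x$hotspot_ids), x$hotspot_pct))
  invisible(x)
}

#' Percent natural cover within a circular window
#'
#' Per cell: 100 x (natural cells with center within `radius_m`) / (cells
#' within `radius_m`), counting only in-extent cells; the analysis buffer
#' ring participates as neighbours.
#'
#' @param mask 0/1 natural mask (e.g. [natural_mask()]).
#' @param radius_m window radius (default 1000).
#' @param resolution_m cell size in m.
#' @return matrix of percentages.
#' @export
natural_cover_pct <- function(mask, radius_m = 1000, resolution_m = 30) {
  k <- disc_kernel(radius_m, resolution_m)
  100 * focal_weighted_mean(mask, k)
}

#' Mean natural cover around a field centroid
#'
#' Mean of the per-pixel cover raster over cells whose centers lie within
#' `radius_m` of the centroid — the second stage of the two-stage focal
#' statistic (per-pixel window first, then the centroid average).
#'
#' @param cover raster from [natural_cover_pct()].
#' @param grid the raster's grid.
#' @param centroid_x,centroid_y field centroid coordinates (vectorized).
#' @param radius_m radius in m (default 1000).
#' @return numeric vector of mean percentages.
#' @export
field_natural_cover <- function(cover, grid, centroid_x, centroid_y,
                                radius_m = 1000) {
  cx <- cell_centers_x(grid); cy <- cell_centers_y(grid)
  vapply(seq_along(centroid_x), function(i) {
    dc <- which(abs(cx - centroid_x[i]) <= radius_m)
    dr <- which(abs(cy - centroid_y[i]) <= radius_m)
    if (!length(dc) || !length(dr)) stop("centroid outside the raster extent")
    dx <- cx[dc] - centroid_x[i]
    dy <- cy[dr] - centroid_y[i]
    inside <- outer(dy^2, dx^2, "+") <= radius_m^2
    mean(cover[dr, dc, drop = FALSE][inside])
  }, numeric(1))
}

#' Restoration-priority ranking by surrounding natural cover
#'
#' Fields are binned by mean natural cover within 1 km of their centroid:
#' high priority below 5%, intermediate 5-10%, low 10-20%, no priority at
#' 20% or more; category areas are reported as % of the agricultural zone.
#'
#' @param field_cover per-field mean cover (%).
#' @param area_ha per-field areas.
#' @param ag_zone_ha total agricultural-zone area used as the denominator
#'   (default: sum of field areas).
#' @param field_id per-field ids.
#' @return a `bs_priority` list: `fields` (id, cover, category), `summary`
#'   (category, total_ha, pct).
#' @export
priority_ranking <- function(field_cover, area_ha,
                             ag_zone_ha = sum(area_ha),
                             field_id = seq_along(field_cover)) {
  lev <- c("high", "intermediate", "low", "none")
  cat <- cut(field_cover, breaks = c(-Inf, 5, 10, 20, Inf),
             labels = lev, right = FALSE)
  tot <- tapply(area_ha, cat, sum, default = 0)[lev]
  structure(list(fields = data.frame(field_id = field_id,
                                     cover_pct = field_cover, category = cat),
                 summary = data.frame(category = factor(lev, levels = lev),
                                      total_ha = as.numeric(tot),
                                      pct = 100 * as.numeric(tot) / ag_zone_ha)),
            class = "bs_priority")
}

#' @export
print.bs_priority <- function(x, ...) {
  cat("<bs_priority> % of agricultural zone by category:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Supply-to-demand ratio raster
#'
#' Scaled supply over scaled demand, defined only where the raw
#' (unscaled) demand is positive; elsewhere NA. The ratio is a relative
#' comparison device across scenarios, not an absolute deficit measure.
#'
#' @param supply_scaled min-max-scaled supply raster.
#' @param demand a `bs_demand` (its `normalized` and raw `raster` are
#'   used).
#' @return matrix with NA outside demand-positive cells.
#' @export
sd_ratio <- function(supply_scaled, demand) {
  out <- matrix(NA_real_, nrow(supply_scaled), ncol(supply_scaled))
  pos <- demand$raster > 0
  out[pos] <- supply_scaled[pos] / demand$normalized[pos]
  out
}

#' Aggregate the S/D ratio on a 1-km grid
#'
#' Tiles the non-buffer territory into square blocks (1 km by default)
#' anchored at the core's north-west corner, keeps blocks overlapping the
#' agricultural region by at least `min_overlap`, averages the defined S/D
#' cells per block, and reports the percentage of retained blocks with
#' mean S/D >= 1. Retained blocks with no defined-ratio cell are excluded
#' from the denominator (and counted in `n_empty`).
#'
#' @param sd S/D raster from [sd_ratio()].
#' @param lulc the scenario's `bs_lulc` (for grid, buffer and core).
#' @param ag_mask logical agricultural-region mask.
#' @param cell_km block edge in km (default 1).
#' @param min_overlap minimum agricultural fraction to retain a block
#'   (default 0.25).
#' @return a `bs_sdgrid` list: `blocks` (block row/col, ag fraction, mean
#'   S/D, retained), `pct_ge1`, `n_retained`, `n_empty`.
#' @export
aggregate_sd <- function(sd, lulc, ag_mask, cell_km = 1, min_overlap = 0.25) {
  g <- lulc$grid; b <- lulc$buffer_cells
  core <- core_mask(lulc)
  per <- cell_km * 1000 / g$resolution
  idx <- which(core)
  r <- ((idx - 1) %% g$n_rows) + 1
  cc <- ((idx - 1) %/% g$n_rows) + 1
  br <- floor((r - b - 1) / per)
  bc <- floor((cc - b - 1) / per)
  key <- paste(br, bc)
  agg <- data.frame(key = key, ag = ag_mask[idx], sd = sd[idx])
  sp <- split(agg, agg$key)
  blocks <- do.call(rbind, lapply(sp, function(d) {
    def <- !is.na(d$sd)
    data.frame(key = d$key[1], n_cells = nrow(d), ag_fraction = mean(d$ag),
               n_defined = sum(def),
               mean_sd = if (any(def)) mean(d$sd[def]) else NA_real_)
  }))
  blocks$retained <- blocks$ag_fraction >= min_overlap
  if (!any(blocks$retained)) stop("no 1-km blocks retained (agricultural overlap < ",
                                  min_overlap, " everywhere)")
  use <- blocks$retained & blocks$n_defined > 0
  structure(list(blocks = blocks,
                 pct_ge1 = 100 * mean(blocks$mean_sd[use] >= 1),
                 n_retained = sum(blocks$retained),
                 n_empty = sum(blocks$retained & blocks$n_defined == 0)),
            class = "bs_sdgrid")
}

#' @export
print.bs_sdgrid <- function(x, ...) {
  cat(sprintf("<bs_sdgrid> %d retained 1-km blocks (%d without demand); %.1f%% with mean S/D >= 1\n",
              x$n_retained, x$n_empty, x$pct_ge1))
  invisible(x)
}

field_mean_raster <- function(raster, labels, field_id) {
  vals <- raster[labels > 0]
  labs <- labels[labels > 0]
  mm <- tapply(vals, labs, mean)
  out <- as.numeric(mm[as.character(field_id)])
  out[is.na(out)] <- 0   # fields too small to own a cell center
  out
}

#' Assess one scenario
#'
#' Runs the supply model on the scenario's LULC, forms the S/D ratio
#' against the (scenario-invariant) demand map, aggregates it on the 1-km
#' grid, computes the two-stage natural-cover statistic and the priority
#' ranking, and classifies fields into the bivariate supply-demand matrix.
#'
#' @param scenario a `bs_scenario`.
#' @param registry field registry (with marginal flags set).
#' @param demand a `bs_demand` built from the baseline (demand is the same
#'   for all scenarios by construction).
#' @param labels field-label raster.
#' @param guild guild table.
#' @param season season for the supply model (default "summer").
#' @param radius_m natural-cover radius (default 1000).
#' @param cutoff kernel truncation threshold.
#' @return a `bs_assessment` list with `supply`, `sd_grid`, `pct_sd_ge1`,
#'   `bivariate`, `priority`, `field_cover`, `scenario_name`, `ledger`.
#' @export
assess_scenario <- function(scenario, registry, demand,
                            labels = rasterize_fields(registry, scenario$lulc$grid),
                            guild = default_guild(), season = "summer",
                            radius_m = 1000, cutoff = 1e-3) {
  lulc <- scenario$lulc
  supply <- supply_index(lulc, guild = guild, season = season, cutoff = cutoff)
  sd <- sd_ratio(supply$normalized, demand)
  agg <- aggregate_sd(sd, lulc, agricultural_mask(lulc, labels))
  cover <- natural_cover_pct(natural_mask(lulc), radius_m = radius_m,
                             resolution_m = lulc$grid$resolution)
  fa <- registry$fields
  fcov <- stats::setNames(
    field_natural_cover(cover, lulc$grid, fa$centroid_x, fa$centroid_y,
                        radius_m = radius_m),
    as.character(fa$field_id))
  prio <- priority_ranking(as.numeric(fcov), fa$area_ha,
                           ag_zone_ha = sum(fa$area_ha),
                           field_id = fa$field_id)
  fsup <- field_mean_raster(supply$normalized, labels, fa$field_id)
  dem <- demand$fields$demand[match(fa$field_id, demand$fields$field_id)]
  biv <- bivariate_matrix(fsup, dem, fa$area_ha, field_id = fa$field_id)
  structure(list(scenario_name = scenario$name, ledger = scenario$ledger,
                 restored_fraction = scenario$restored_fraction,
                 supply = supply, sd_grid = agg, pct_sd_ge1 = agg$pct_ge1,
                 bivariate = biv, priority = prio,
                 field_cover = fcov, cover_raster = cover),
            class = "bs_assessment")
}

#' Compare assessed scenarios against a baseline
#'
#' @param assessments list of `bs_assessment` objects (must include the
#'   baseline).
#' @param baseline name of the baseline scenario (default
#'   "no_restoration").
#' @return data.frame: one row per scenario with restored areas, % 1-km
#'   blocks with S/D >= 1 and its delta vs. the baseline, and the priority
#'   percentages.
#' @export
compare_scenarios <- function(assessments, baseline = "no_restoration") {
  nms <- vapply(assessments, `[[`, character(1), "scenario_name")
  if (!baseline %in% nms) stop("baseline scenario '", baseline, "' not in the list")
  base <- assessments[[match(baseline, nms)]]
  rows <- lapply(assessments, function(a) {
    pr <- stats::setNames(a$priority$summary$pct,
                          paste0("pct_priority_", a$priority$summary$category))
    cbind(data.frame(scenario = a$scenario_name,
                     reforested_ha = a$ledger$reforested_ha,
                     strips_ha = a$ledger$strips_ha,
                     restored_ha = a$ledger$restored_ha,
                     restored_pct_territory = 100 * a$restored_fraction,
                     pct_sd_ge1 = a$pct_sd_ge1,
                     delta_pct_sd_ge1 = a$pct_sd_ge1 - base$pct_sd_ge1,
                     hotspot_pct = a$bivariate$hotspot_pct),
          as.data.frame(as.list(pr)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
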