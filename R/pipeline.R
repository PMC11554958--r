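#' Default run configuration
#'
#' All stage parameters with their reference defaults: 5-yr abandonment
#' window, p <= 0.05 NDVI trend, 25-m edge removal, 0.15-ha patch filter,
#' 30% field-degraded rule, 5-m strips, 3% mixed-strategy target, 50-m
#' maximal-scenario exclusion, 1-km radii, summer season.
#'
#' @param seed integer seed driving the synthetic landscape.
#' @param ... overrides for any config entry (`synthetic` takes a list of
#'   [synth_config()] arguments).
#' @return a config list for [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    synthetic = list(),             # args to synth_config(); seed injected
    abandonment_window = 5,
    p_max = 0.05,
    erosion_m = 25,
    min_patch_ha = 0.15,
    degraded_fraction = 0.30,
    strip_width_m = 5,
    target_fraction = 0.03,
    exclusion_m = 50,
    radius_m = 1000,
    cover_max_pct = 5,
    season = "summer",
    kernel_cutoff = 1e-3,
    scenarios = c("no_restoration", "reforest_marginal", "flower_strips",
                  "mixed", "maximal"))
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full restoration-assessment pipeline
#'
#' Generate (or load) the landscape, detect marginal lands, build the
#' baseline supply/demand assessment, construct the requested restoration
#' scenarios, assess each, and write the comparison table plus a
#' machine-readable run manifest. Reruns with the same config are
#' bit-identical.
#'
#' @param config list from [default_run_config()]; `config$inputs` may
#'   instead name files (`lulc`, `classes`, `registry`, `history`,
#'   `ndvi_dir`) to load a real landscape.
#' @param out_dir output directory (created); NULL skips all file output.
#' @return (invisibly) list with `bundle`, `report`, `demand`,
#'   `scenarios`, `assessments`, `comparison`, `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
                                         as.numeric(Sys.time() - t0, "secs"), msg))
  if (!is.null(config$inputs)) {
    stage("loading landscape from files")
    inp <- config$inputs
    lulc <- read_lulc(inp$lulc, inp$classes)
    registry <- read_registry(inp$registry, inp$history)
    ndvi <- read_ndvi_stack(inp$ndvi_dir)
    labels <- rasterize_fields(registry, lulc$grid)
    bundle <- structure(list(lulc = lulc, registry = registry, labels = labels,
                             ndvi = ndvi, truth = NULL, config = NULL),
                        class = "bs_bundle")
  } else {
    stage("generating synthetic landscape")
    sargs <- config$synthetic
    sargs$seed <- config$seed
    bundle <- generate_landscape(do.call(synth_config, sargs))
  }
  stage("detecting marginal lands")
  report <- marginal_report(bundle,
                            window = config$abandonment_window,
                            p_max = config$p_max,
                            min_patch_ha = config$min_patch_ha,
                            fraction = config$degraded_fraction,
                            erosion_m = config$erosion_m)
  registry <- set_marginal_flags(bundle$registry,
                                 abandoned = report$abandoned_ids,
                                 degraded = report$degraded_ids)
  labels <- bundle$labels
  lulc <- bundle$lulc
  stage("mapping pollination demand")
  demand <- demand_map(registry, lulc$grid, labels = labels,
                       core = core_mask(lulc))
  guild <- default_guild()

  stage("assessing baseline")
  scen <- list(no_restoration = scenario_no_restoration(lulc))
  asmt <- list(no_restoration = assess_scenario(
    scen$no_restoration, registry, demand, labels = labels, guild = guild,
    season = config$season, radius_m = config$radius_m,
    cutoff = config$kernel_cutoff))
  base <- asmt$no_restoration

  for (nm in setdiff(config$scenarios, "no_restoration")) {
    stage(paste("building + assessing scenario", nm))
    scen[[nm]] <- switch(nm,
      reforest_marginal = scenario_reforest_marginal(lulc, registry, report,
                                                     labels = labels),
      flower_strips = scenario_flower_strips(lulc, registry, report,
                                             labels = labels,
                                             width_m = config$strip_width_m),
      mixed = scenario_mixed(lulc, registry, report,
                             hotspot_ids = base$bivariate$hotspot_ids,
                             field_cover = base$field_cover,
                             labels = labels,
                             target_fraction = config$target_fraction,
                             radius_m = config$radius_m,
                             cover_max_pct = config$cover_max_pct,
                             width_m = config$strip_width_m),
      maximal = scenario_maximal(lulc, registry, report, labels = labels,
                                 exclusion_m = config$exclusion_m,
                                 width_m = config$strip_width_m),
      stop("unknown scenario: ", nm))
    asmt[[nm]] <- assess_scenario(scen[[nm]], registry, demand,
                                  labels = labels, guild = guild,
                                  season = config$season,
                                  radius_m = config$radius_m,
                                  cutoff = config$kernel_cutoff)
  }
  comparison <- compare_scenarios(asmt)
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "inputs")],
                   territory_ha = territory_ha(lulc),
                   agricultural_zone_ha = sum(registry$fields$area_ha),
                   n_fields = nrow(registry$fields),
                   abandoned_ha = report$total_abandoned_ha,
                   degraded_ha = report$total_degraded_ha,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("beescape")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(demand$fields, file.path(out_dir, "field_demand.csv"),
                     row.names = FALSE)
    for (nm in names(scen)) {
      led <- scen[[nm]]$ledger
      utils::write.csv(data.frame(scenario = nm,
                                  reforested_ha = led$reforested_ha,
                                  strips_ha = led$strips_ha),
                       file.path(out_dir, paste0("ledger_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  stage("done")
  invisible(list(bundle = bundle, report = report, registry = registry,
                 demand = demand, scenarios = scen, assessments = asmt,
                 comparison = comparison, manifest = manifest))
}
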