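#' Configuration for the synthetic landscape generator
#'
#' The generator emulates an intensive corn/soy agricultural county of the
#' southern-Quebec type: about 60% of the territory cultivated, mean field
#' size 6.2 +/- 7.1 ha, a minority of pollinator-dependent crops, a spatial
#' cluster of abandoned fields, and an annual NDVI stack in which planted
#' degraded fields carry a known linear decline. Every downstream stage can
#' therefore be tested against ground truth.
#'
#' @param seed integer RNG seed; bundles are byte-identical per seed.
#' @param extent_km territory extent (width, height) in km, buffer excluded.
#' @param resolution cell size in m (default 30).
#' @param buffer_m analysis-buffer width (default 2000).
#' @param fraction_agricultural,fraction_forest,fraction_wetland,fraction_builtup
#'   target cover fractions; the remainder becomes old field / shrubland.
#' @param field_area_mean_ha,field_area_sd_ha target field-size distribution
#'   (log-normal moments; defaults 6.2 and 7.1 ha).
#' @param crop_mix data.frame (crop_code, freq, dependency_class) used to
#'   draw each field's main crop per year; see [default_crop_mix()].
#' @param n_years_history length of the cultivation-history window (10).
#' @param history_end_year final history year (default 2021).
#' @param n_years_ndvi NDVI stack length in years (default 22, >= 3).
#' @param n_abandoned_fields,n_degraded_fields number of fields planted with
#'   each condition.
#' @param ndvi_decline_per_year NDVI trend planted in degraded fields
#'   (negative; default -0.01 per year).
#' @param ndvi_noise_sd Gaussian noise SD on annual NDVI (default 0.02).
#' @param ndvi_baseline mean NDVI of an undisturbed series (default 0.75).
#' @param degraded_cell_fraction fraction of a planted field's cells given
#'   the declining trend (default 0.6, so that >= 30% of the *full* field
#'   area still shows the trend after the 1-cell edge erosion applied by the
#'   detection stage).
#' @param abandonment_window years of terminal non-cultivation planted in
#'   abandoned fields (default 5).
#' @return a validated `bs_synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         extent_km = c(6, 6),
                         resolution = 30,
                         buffer_m = 2000,
                         fraction_agricultural = 0.60,
                         fraction_forest = 0.20,
                         fraction_wetland = 0.02,
                         fraction_builtup = 0.15,
                         field_area_mean_ha = 6.2,
                         field_area_sd_ha = 7.1,
                         crop_mix = default_crop_mix(),
                         n_years_history = 10,
                         history_end_year = 2021,
                         n_years_ndvi = 22,
                         n_abandoned_fields = 20,
                         n_degraded_fields = 3,
                         ndvi_decline_per_year = -0.01,
                         ndvi_noise_sd = 0.02,
                         ndvi_baseline = 0.75,
                         degraded_cell_fraction = 0.6,
                         abandonment_window = 5) {
  fr <- c(fraction_agricultural, fraction_forest, fraction_wetland, fraction_builtup)
  if (any(fr < 0) || sum(fr) > 1)
    stop("cover fractions must be >= 0 and sum to <= 1")
  if (n_years_ndvi < 3) stop("n_years_ndvi must be >= 3 (regression needs >= 3 points)")
  if (ndvi_noise_sd < 0) stop("ndvi_noise_sd must be >= 0")
  if (abandonment_window > n_years_history)
    stop("abandonment_window cannot exceed the history length")
  cfg <- list(seed = as.integer(seed), extent_km = extent_km,
              resolution = resolution, buffer_m = buffer_m,
              fraction_agricultural = fraction_agricultural,
              fraction_forest = fraction_forest,
              fraction_wetland = fraction_wetland,
              fraction_builtup = fraction_builtup,
              field_area_mean_ha = field_area_mean_ha,
              field_area_sd_ha = field_area_sd_ha,
              crop_mix = crop_mix,
              n_years_history = n_years_history,
              history_end_year = history_end_year,
              n_years_ndvi = n_years_ndvi,
              n_abandoned_fields = n_abandoned_fields,
              n_degraded_fields = n_degraded_fields,
              ndvi_decline_per_year = ndvi_decline_per_year,
              ndvi_noise_sd = ndvi_noise_sd,
              ndvi_baseline = ndvi_baseline,
              degraded_cell_fraction = degraded_cell_fraction,
              abandonment_window = abandonment_window)
  structure(cfg, class = "bs_synth_config")
}

#' Packaged crop mix for the synthetic generator
#'
#' Corn/soy dominance (~76% of field-years) with cereals, hay and a minority
#' of pollinator-dependent crops (vegetables, canola, berries, orchards).
#'
#' @return data.frame (crop_code, freq, dependency_class).
#' @export
default_crop_mix <- function() {
  data.frame(
    crop_code = c("corn", "soybean", "wheat", "hay",
                  "vegetables", "canola", "berries", "orchard"),
    freq = c(0.40, 0.36, 0.08, 0.06, 0.05, 0.02, 0.02, 0.01),
    dependency_class = c("none", "little", "none", "none",
                         "modest", "great", "great", "essential"),
    stringsAsFactors = FALSE)
}

# Two-phase rectangular partition of the grid into parcels. Phase 1 splits
# the extent into chunky blocks of roughly ten field-areas by recursive cuts
# across the long axis. Phase 2 slices each block into parallel lots that
# span the block's shorter dimension, drawing lot areas from a log-normal
# with the configured mean/SD. The result mimics the elongated long-lot
# ("rang") field pattern of St. Lawrence lowland agriculture, where ~6-ha
# fields commonly run several hundred meters along one axis. Deterministic
# given the RNG state. Returns a data.frame of cell bounds (r0, r1, c0, c1).
split_rects <- function(n_rows, n_cols, cell_ha, mean_ha, sd_ha, min_side = 3) {
  sdlog <- sqrt(log(1 + (sd_ha / mean_ha)^2))
  meanlog <- log(mean_ha) - sdlog^2 / 2
  blocks <- vector("list", 1024)
  n_blk <- 0L
  stack <- list(c(1L, n_rows, 1L, n_cols))
  while (length(stack)) {
    rect <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    h <- rect[2] - rect[1] + 1L; w <- rect[4] - rect[3] + 1L
    target <- stats::rlnorm(1, meanlog, sdlog)
    if (h * w * cell_ha <= 10 * target || max(h, w) < 2L * min_side) {
      n_blk <- n_blk + 1L
      if (n_blk > length(blocks)) blocks <- c(blocks, vector("list", length(blocks)))
      blocks[[n_blk]] <- rect
      next
    }
    frac <- stats::runif(1, 0.35, 0.65)
    if (h >= w) {
      cut <- min(max(round(h * frac), min_side), h - min_side)
      stack[[length(stack) + 1L]] <- c(rect[1], rect[1] + cut - 1L, rect[3], rect[4])
      stack[[length(stack) + 1L]] <- c(rect[1] + cut, rect[2], rect[3], rect[4])
    } else {
      cut <- min(max(round(w * frac), min_side), w - min_side)
      stack[[length(stack) + 1L]] <- c(rect[1], rect[2], rect[3], rect[3] + cut - 1L)
      stack[[length(stack) + 1L]] <- c(rect[1], rect[2], rect[3] + cut, rect[4])
    }
  }
  out <- vector("list", 4096)
  n_out <- 0L
  for (k in seq_len(n_blk)) {
    rect <- blocks[[k]]
    h <- rect[2] - rect[1] + 1L; w <- rect[4] - rect[3] + 1L
    along_cols <- h <= w          # lots span the block's shorter dimension
    depth <- min(h, w)
    len <- max(h, w)
    col_ha <- depth * cell_ha     # area of one cell-wide slice
    pos <- 0L
    while (pos < len) {
      a <- stats::rlnorm(1, meanlog, sdlog)
      # frontage: at least 2 cells, and wide enough to cap aspect near 8
      fi <- max(2L, as.integer(ceiling(depth / 8)), as.integer(round(a / col_ha)))
      fi <- min(fi, len - pos)
      if (len - pos - fi < 2L) fi <- len - pos
      lot <- if (along_cols)
        c(rect[1], rect[2], rect[3] + pos, rect[3] + pos + fi - 1L)
      else
        c(rect[1] + pos, rect[1] + pos + fi - 1L, rect[3], rect[4])
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- lot
      pos <- pos + fi
    }
  }
  m <- do.call(rbind, out[seq_len(n_out)])
  data.frame(r0 = m[, 1], r1 = m[, 2], c0 = m[, 3], c1 = m[, 4])
}

rect_to_polygon <- function(grid, r0, r1, c0, c1) {
  res <- grid$resolution
  xmin <- grid$origin_x + (c0 - 1) * res
  xmax <- grid$origin_x + c1 * res
  ymax <- grid$origin_y - (r0 - 1) * res
  ymin <- grid$origin_y - r1 * res
  rect_polygon(xmin, ymin, xmax, ymax)
}

#' Generate a synthetic landscape bundle with known ground truth
#'
#' Builds the territory by recursive rectangular splitting of the full
#' extent into parcels, assigns parcels to cover types so realized core
#' fractions match the configured ones (stratified between territory and
#' buffer), samples each field's cultivation history from the crop mix,
#' plants a spatial cluster of abandoned fields (uncultivated in the final
#' window years) and a set of degraded fields (contiguous in-field block
#' with a linear NDVI decline), and simulates the annual NDVI stack.
#'
#' @param config a [synth_config()].
#' @return a `bs_bundle`: list with `lulc`, `registry`, `labels` (field
#'   label raster), `ndvi` (list grid/years/values) and `truth` (planted
#'   abandoned and degraded field ids).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "bs_synth_config"))
  set.seed(config$seed)
  res <- config$resolution
  core_rows <- round(config$extent_km[2] * 1000 / res)
  core_cols <- round(config$extent_km[1] * 1000 / res)
  b <- as.integer(ceiling(config$buffer_m / res))
  n_rows <- core_rows + 2L * b; n_cols <- core_cols + 2L * b
  grid <- landscape_grid(n_rows, n_cols, resolution = res)
  classes <- default_class_table()
  cid <- function(nm) classes$class_id[match(nm, classes$name)]

  rects <- split_rects(n_rows, n_cols, cell_area_ha(grid),
                       config$field_area_mean_ha, config$field_area_sd_ha)
  rects$area_ha <- (rects$r1 - rects$r0 + 1) * (rects$c1 - rects$c0 + 1) *
    cell_area_ha(grid)
  rects$core <- with(rects, (r0 + r1) / 2 > b & (r0 + r1) / 2 <= n_rows - b &
                       (c0 + c1) / 2 > b & (c0 + c1) / 2 <= n_cols - b)

  # Cover assignment is spatially clustered, as in real agricultural
  # counties: natural classes concentrate around a few "nature" centers and
  # built-up around "urban" centers, leaving open crop plains with very low
  # surrounding natural cover. Parcels are ranked by smooth blob scores and
  # filled greedily per class; assignment is stratified between territory
  # and buffer so the realized core fractions track the configured ones to
  # within one parcel.
  blob_score <- function(n_centers, bw_cells) {
    ctr <- cbind(stats::runif(n_centers, 1, n_rows),
                 stats::runif(n_centers, 1, n_cols))
    vapply(seq_len(nrow(rects)), function(i) {
      d2 <- (ctr[, 1] - ctr_r0[i])^2 + (ctr[, 2] - ctr_c0[i])^2
      max(exp(-d2 / (2 * bw_cells^2)))
    }, numeric(1)) + stats::runif(nrow(rects), 0, 0.02)
  }
  ctr_r0 <- (rects$r0 + rects$r1) / 2
  ctr_c0 <- (rects$c0 + rects$c1) / 2
  diag_cells <- sqrt(n_rows^2 + n_cols^2)
  nature_score <- blob_score(4, diag_cells / 8)
  urban_score <- blob_score(2, diag_cells / 10)
  targets <- c(builtup = config$fraction_builtup,
               forest = config$fraction_forest,
               wetland = config$fraction_wetland,
               oldfield = max(0, 1 - config$fraction_agricultural -
                                config$fraction_forest -
                                config$fraction_wetland -
                                config$fraction_builtup))
  rects$cover <- NA_character_
  for (stratum in c(TRUE, FALSE)) {
    in_str <- which(rects$core == stratum)
    total <- sum(rects$area_ha[in_str])
    take <- function(pool, score, cap) {
      ord <- pool[order(-score[pool])]
      cum <- cumsum(rects$area_ha[ord])
      ord[cum <= cap | c(0, utils::head(cum, -1)) < cap]
    }
    got_urban <- take(in_str, urban_score, targets["builtup"] * total)
    rects$cover[got_urban] <- "builtup"
    left <- setdiff(in_str, got_urban)
    for (cls in c("forest", "wetland", "oldfield")) {
      got <- take(left, nature_score, targets[cls] * total)
      rects$cover[got] <- cls
      left <- setdiff(left, got)
    }
    rects$cover[left] <- "agriculture"
  }

  is_field <- rects$cover == "agriculture" & rects$core
  field_idx <- which(is_field)
  n_fields <- length(field_idx)
  if (config$n_abandoned_fields + config$n_degraded_fields > n_fields)
    stop("infeasible config: more planted marginal fields (",
         config$n_abandoned_fields + config$n_degraded_fields,
         ") than fields (", n_fields, ")")
  field_ids <- stats::setNames(seq_len(n_fields), field_idx)

  # cultivation history: one main crop per field-year, iid from the mix
  years <- (config$history_end_year - config$n_years_history + 1):config$history_end_year
  mix <- config$crop_mix
  crops <- matrix(sample(mix$crop_code, n_fields * length(years), replace = TRUE,
                         prob = mix$freq),
                  nrow = n_fields)

  # abandoned cluster: a seed field and its nearest neighbours by centroid.
  # The seed sits where the nature score is highest among fields: land
  # abandonment concentrates on marginal soils near existing natural areas,
  # not in the middle of the productive plain.
  ctr_r <- (rects$r0 + rects$r1) / 2; ctr_c <- (rects$c0 + rects$c1) / 2
  abandoned_ids <- integer(0)
  if (config$n_abandoned_fields > 0) {
    seed_f <- which.max(nature_score[field_idx])
    d <- (ctr_r[field_idx] - ctr_r[field_idx[seed_f]])^2 +
      (ctr_c[field_idx] - ctr_c[field_idx[seed_f]])^2
    abandoned_ids <- sort(order(d)[seq_len(config$n_abandoned_fields)])
  }

  # degraded fields: big enough that >=30% of the full field area keeps the
  # planted trend after the detection stage's 1-cell edge erosion
  degraded_ids <- integer(0)
  if (config$n_degraded_fields > 0) {
    hh <- rects$r1[field_idx] - rects$r0[field_idx] + 1
    ww <- rects$c1[field_idx] - rects$c0[field_idx] + 1
    eligible <- setdiff(which(pmin(hh, ww) >= 6 & hh * ww >= 45 & hh * ww <= 160),
                        abandoned_ids)
    if (length(eligible) < config$n_degraded_fields)
      stop("infeasible config: only ", length(eligible),
           " fields large enough to plant degradation")
    degraded_ids <- sort(sample(eligible, config$n_degraded_fields))
  }

  hist_list <- vector("list", n_fields)
  for (f in seq_len(n_fields)) {
    cult <- rep(TRUE, length(years))
    crop <- crops[f, ]
    if (f %in% abandoned_ids) {
      tail_idx <- (length(years) - config$abandonment_window + 1):length(years)
      cult[tail_idx] <- FALSE
      crop[tail_idx] <- NA_character_
    }
    hist_list[[f]] <- data.frame(field_id = f, year = years,
                                 cultivated = cult, crop_code = crop,
                                 stringsAsFactors = FALSE)
  }
  history <- do.call(rbind, hist_list)

  # LULC codes
  # LULC floral-crop class reserved for crops that actually feed bees
  # (modest dependency or higher); soy's marginal dependency stays low-floral
  dep_w <- dependency_weight(mix$crop_code, default_dependency_table())
  floral_crop <- dep_w >= 0.25
  codes <- new_raster(grid, cid("oldfield_shrubland"))
  p_dependent <- sum(mix$freq[floral_crop])
  for (i in seq_len(nrow(rects))) {
    code <- switch(rects$cover[i],
      agriculture = NA_integer_,   # filled per field below
      forest = cid("forest"),
      wetland = cid("wetland"),
      builtup = if (stats::runif(1) < 0.5) cid("urban_vegetation") else cid("impervious"),
      oldfield = cid("oldfield_shrubland"))
    if (rects$cover[i] == "agriculture") {
      if (rects$core[i]) {
        f <- field_ids[as.character(i)]
        main <- names(sort(table(crops[f, ]), decreasing = TRUE))[1]
        code <- if (floral_crop[match(main, mix$crop_code)])
          cid("crop_floral") else cid("crop_low_floral")
      } else {
        code <- if (stats::runif(1) < p_dependent)
          cid("crop_floral") else cid("crop_low_floral")
      }
    }
    codes[rects$r0[i]:rects$r1[i], rects$c0[i]:rects$c1[i]] <- code
  }
  lulc <- lulc_map(grid, codes, classes, buffer_m = config$buffer_m)

  polys <- stats::setNames(
    lapply(field_idx, function(i)
      rect_to_polygon(grid, rects$r0[i], rects$r1[i], rects$c0[i], rects$c1[i])),
    as.character(seq_len(n_fields)))
  registry <- field_registry(polys, history)
  labels <- rasterize_fields(registry, grid)

  # NDVI stack: zero-trend noisy series everywhere except the planted
  # degraded blocks, which get the configured decline
  set.seed(config$seed + 1000L)
  slope_m <- new_raster(grid, 0)
  for (f in degraded_ids) {
    i <- field_idx[f]
    h <- rects$r1[i] - rects$r0[i] + 1; w <- rects$c1[i] - rects$c0[i] + 1
    if (w >= h) {
      ncol_block <- ceiling(config$degraded_cell_fraction * w)
      slope_m[rects$r0[i]:rects$r1[i], rects$c0[i]:(rects$c0[i] + ncol_block - 1)] <-
        config$ndvi_decline_per_year
    } else {
      nrow_block <- ceiling(config$degraded_cell_fraction * h)
      slope_m[rects$r0[i]:(rects$r0[i] + nrow_block - 1), rects$c0[i]:rects$c1[i]] <-
        config$ndvi_decline_per_year
    }
  }
  ndvi_years <- (config$history_end_year - config$n_years_ndvi + 1):config$history_end_year
  ndvi <- array(NA_real_, c(n_rows, n_cols, config$n_years_ndvi))
  for (t in seq_len(config$n_years_ndvi)) {
    ndvi[, , t] <- config$ndvi_baseline + slope_m * (t - 1) +
      matrix(stats::rnorm(n_rows * n_cols, 0, config$ndvi_noise_sd), n_rows)
  }

  structure(list(lulc = lulc, registry = registry, labels = labels,
                 ndvi = list(grid = grid, years = ndvi_years, values = ndvi),
                 truth = list(abandoned = abandoned_ids, degraded = degraded_ids),
                 config = config),
            class = "bs_bundle")
}

#' @export
print.bs_bundle <- function(x, ...) {
  cat("<bs_bundle>\n")
  print(x$lulc)
  print(x$registry)
  cat(sprintf("  ndvi: %d years (%d-%d); truth: %d abandoned, %d degraded\n",
              length(x$ndvi$years), min(x$ndvi$years), max(x$ndvi$years),
              length(x$truth$abandoned), length(x$truth$degraded)))
  invisible(x)
}

#' Simulate a single annual NDVI series
#'
#' `value[t] = baseline + slope * (t - 1) + N(0, noise_sd)` for
#' `t = 1..n_years`.
#'
#' @param n_years number of annual values (>= 3).
#' @param baseline intercept (NDVI units).
#' @param slope trend per year.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of length `n_years`.
#' @export
generate_ndvi_series <- function(n_years, baseline, slope, noise_sd, seed = NULL) {
  if (n_years < 3) stop("n_years must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  baseline + slope * (seq_len(n_years) - 1) + stats::rnorm(n_years, 0, noise_sd)
}
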