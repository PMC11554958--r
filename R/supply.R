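#' Pollinator guild table
#'
#' Per-taxon parameters for the foraging-kernel abundance model: typical
#' foraging distance `alpha_m`, nesting-substrate preferences
#' (`nest_<substrate>` columns, each in [0, 1] with at least one positive)
#' and seasonal activity weights (`activity_<season>` columns summing to 1).
#'
#' @param tab data.frame to validate.
#' @return validated data.frame.
#' @export
pollinator_guild <- function(tab) {
  tab <- as.data.frame(tab)
  if (!all(c("taxon", "alpha_m") %in% names(tab)))
    stop("guild table needs taxon and alpha_m columns")
  if (any(tab$alpha_m <= 0)) stop("alpha_m must be > 0")
  nest <- grep("^nest_", names(tab), value = TRUE)
  act <- grep("^activity_", names(tab), value = TRUE)
  if (!length(nest) || !length(act))
    stop("guild table needs nest_<substrate> and activity_<season> columns")
  nm <- as.matrix(tab[nest])
  if (any(nm < 0 | nm > 1)) stop("nesting preferences must lie in [0, 1]")
  if (any(rowSums(nm) == 0)) stop("every taxon needs a positive nesting preference")
  am <- as.matrix(tab[act])
  if (any(abs(rowSums(am) - 1) > 1e-9))
    stop("activity weights must sum to 1 per taxon")
  tab
}

#' Packaged ten-genus guild table
#'
#' Illustrative parameters for ten wild-bee genera commonly recorded in
#' northeastern North American agricultural landscapes (Bombus,
#' Lasioglossum, Andrena, Halictus, Megachile, Ceratina, Hylaeus, Osmia,
#' Agapostemon, Melissodes), with foraging distances spanning 100-1500 m
#' and literature-style nesting/seasonal weights. The values are
#' illustrative defaults, not a reproduction of any region-specific expert
#' elicitation; replace the CSV for real applications.
#'
#' @return validated guild data.frame.
#' @export
default_guild <- function() {
  path <- system.file("extdata", "guild.csv", package = "beescape")
  pollinator_guild(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-cell nesting suitability for a taxon
#'
#' `HN(x) = max_j class_nesting(l(x), j) * preference_j` over nesting
#' substrates j.
#'
#' @param lulc a `bs_lulc` whose class table has a `nest_<substrate>`
#'   column for every substrate the taxon uses.
#' @param taxon one guild-table row (data.frame or list).
#' @return matrix in [0, 1].
#' @export
pixel_nesting_suitability <- function(lulc, taxon) {
  prefs <- taxon[grep("^nest_", names(taxon))]
  hn <- new_raster(lulc$grid, 0)
  for (sub in names(prefs)) {
    w <- as.numeric(prefs[[sub]])
    if (w == 0) next
    if (!sub %in% names(lulc$class_table))
      stop("class table lacks nesting substrate column: ", sub)
    hn <- pmax(hn, class_row(lulc, sub) * w)
  }
  hn
}

#' Per-cell floral availability for a season
#'
#' Looks up `floral_<season>` in the class table; the taxon's seasonal
#' activity weight is applied at abundance aggregation, not here.
#'
#' @param lulc a `bs_lulc`.
#' @param season season name (e.g. "summer").
#' @return matrix in [0, 1].
#' @export
pixel_floral_value <- function(lulc, season) {
  col <- paste0("floral_", season)
  if (!col %in% names(lulc$class_table)) stop("unknown season: ", season)
  class_row(lulc, col)
}

#' Exponential foraging kernel
#'
#' `w(d) = exp(-d / alpha_m)` with d the center-to-center Euclidean
#' distance, truncated where the relative weight drops below `cutoff`
#' (radius `alpha * ln(1/cutoff)`). The kernel is radially symmetric and
#' unnormalized; normalization happens per cell over the window in
#' [foraging_average()].
#'
#' @param alpha_m typical foraging distance in m (> resolution/10).
#' @param resolution_m cell size in m.
#' @param cutoff relative-weight truncation threshold (default 1e-3).
#' @return odd-dimensioned weight matrix.
#' @export
exponential_kernel <- function(alpha_m, resolution_m, cutoff = 1e-3) {
  if (alpha_m <= 0) stop("alpha_m must be > 0")
  if (alpha_m < resolution_m / 10)
    stop("alpha_m (", alpha_m, " m) undersampled at ", resolution_m, " m resolution")
  r <- ceiling(alpha_m * log(1 / cutoff) / resolution_m)
  off <- (-r):r
  d <- sqrt(outer(off^2, off^2, "+")) * resolution_m
  w <- exp(-d / alpha_m)
  w[w < cutoff] <- 0
  w
}

#' Distance-weighted foraging average
#'
#' `out(x) = sum_m v(m) w(d(x, m)) / sum_m w(d(x, m))`, both sums over
#' in-extent cells within the kernel support.
#'
#' @param v finite value raster.
#' @param kernel weight kernel from [exponential_kernel()].
#' @param denom optional cached denominator (all-ones convolution).
#' @return matrix of weighted means.
#' @export
foraging_average <- function(v, kernel, denom = NULL)
  focal_weighted_mean(v, kernel, denom = denom)

#' Relative wild-bee abundance for one taxon
#'
#' Lonsdorf-style two-pass model: the source strength of a nest cell is its
#' nesting suitability times the distance-weighted floral resources around
#' it, `P(x) = HN(x) * favg(HF(., season))(x)`; the abundance visiting a
#' cell is the distance-weighted average of source strengths,
#' `A(o) = favg(P)(o)`, scaled by the taxon's seasonal activity weight.
#'
#' @param lulc a `bs_lulc`.
#' @param taxon one guild row.
#' @param season season name.
#' @param cutoff kernel truncation (default 1e-3).
#' @return abundance matrix (>= 0).
#' @export
taxon_abundance <- function(lulc, taxon, season = "summer", cutoff = 1e-3) {
  kernel <- exponential_kernel(as.numeric(taxon$alpha_m),
                               lulc$grid$resolution, cutoff = cutoff)
  denom <- conv2_same(new_raster(lulc$grid, 1), kernel)
  hn <- pixel_nesting_suitability(lulc, taxon)
  hf <- pixel_floral_value(lulc, season)
  p <- hn * foraging_average(hf, kernel, denom = denom)
  act_col <- paste0("activity_", season)
  act <- if (act_col %in% names(taxon)) as.numeric(taxon[[act_col]]) else 1
  foraging_average(p, kernel, denom = denom) * act
}

#' Landscape pollination-supply index
#'
#' Unweighted mean of per-taxon relative abundances for the chosen season
#' (the summer map is what the assessment uses), with a min-max-normalized
#' copy computed over the non-buffer territory.
#'
#' @param lulc a `bs_lulc`.
#' @param guild guild table (default [default_guild()]).
#' @param season season name (default "summer").
#' @param cutoff kernel truncation threshold.
#' @return a `bs_supply` list: `raster` (mean abundance), `normalized`
#'   (min-max scaled over the core), `norm_record` (min, max used),
#'   `season`, `n_taxa`.
#' @export
supply_index <- function(lulc, guild = default_guild(), season = "summer",
                         cutoff = 1e-3) {
  guild <- pollinator_guild(guild)
  if (!nrow(guild)) stop("guild must contain at least one taxon")
  acc <- new_raster(lulc$grid, 0)
  for (i in seq_len(nrow(guild)))
    acc <- acc + taxon_abundance(lulc, guild[i, ], season = season,
                                 cutoff = cutoff)
  acc <- acc / nrow(guild)
  core <- core_mask(lulc)
  rng <- range(acc[core])
  structure(list(raster = acc,
                 normalized = minmax_scale(acc, core),
                 norm_record = list(min = rng[1], max = rng[2]),
                 season = season, n_taxa = nrow(guild)),
            class = "bs_supply")
}

#' @export
print.bs_supply <- function(x, ...) {
  cat(sprintf("<bs_supply> %s, %d taxa; core range [%.4g, %.4g]\n",
              x$season, x$n_taxa, x$norm_record$min, x$norm_record$max))
  invisible(x)
}
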