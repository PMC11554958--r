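# Shared fixtures and independent oracles. The oracles recompute results by
# brute force (double loops, direct counting) and never call the package's
# convolution/averaging path.

small_config <- function(...) {
  synth_config(seed = 7, extent_km = c(3, 3), buffer_m = 1000,
               n_abandoned_fields = 6, n_degraded_fields = 3, ...)
}

# memoized: generating the 3x3-km bundle once per test run
.small_cache <- new.env(parent = emptyenv())
small_bundle <- function() {
  if (is.null(.small_cache$bundle))
    .small_cache$bundle <- generate_landscape(small_config())
  .small_cache$bundle
}

# memoized full-scale run: 6x6-km territory (200x200 core cells), all five
# scenarios, reference parameters throughout
full_run <- function() {
  if (is.null(.small_cache$full))
    .small_cache$full <- suppressMessages(
      run_pipeline(default_run_config(seed = 1), out_dir = NULL))
  .small_cache$full
}

# uniform toy LULC map on a fresh grid (no buffer unless asked)
toy_lulc <- function(codes, buffer_m = 0) {
  codes <- as.matrix(codes)
  g <- landscape_grid(nrow(codes), ncol(codes), resolution = 30)
  lulc_map(g, codes, default_class_table(), buffer_m = buffer_m)
}

# a single rectangular field registry: one field of nr x nc cells starting
# at cell (r0, c0) on `grid`, cultivated with `crop` every history year
rect_field_registry <- function(grid, r0, c0, nr, nc, crop = "canola",
                                years = 2012:2021, id = 1) {
  res <- grid$resolution
  poly <- rect_polygon(grid$origin_x + (c0 - 1) * res,
                       grid$origin_y - (r0 - 1 + nr) * res,
                       grid$origin_x + (c0 - 1 + nc) * res,
                       grid$origin_y - (r0 - 1) * res)
  hist <- data.frame(field_id = id, year = years, cultivated = TRUE,
                     crop_code = crop, stringsAsFactors = FALSE)
  field_registry(stats::setNames(list(poly), id), hist)
}

# brute-force distance-weighted mean (exponential kernel), double loop
oracle_favg <- function(v, alpha, res, cutoff = 1e-3) {
  nr <- nrow(v); nc <- ncol(v)
  rmax <- ceiling(alpha * log(1 / cutoff) / res)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    num <- 0; den <- 0
    for (rr in max(1, r - rmax):min(nr, r + rmax)) {
      for (cc in max(1, c - rmax):min(nc, c + rmax)) {
        w <- exp(-sqrt((rr - r)^2 + (cc - c)^2) * res / alpha)
        if (w < cutoff) next
        num <- num + v[rr, cc] * w
        den <- den + w
      }
    }
    out[r, c] <- num / den
  }
  out
}

# brute-force taxon abundance: direct class-table lookups + oracle_favg
oracle_abundance <- function(lulc, taxon, season = "summer", cutoff = 1e-3) {
  tab <- lulc$class_table
  idx <- match(as.vector(lulc$codes), tab$class_id)
  nr <- nrow(lulc$codes)
  hn <- matrix(0, nr, ncol(lulc$codes))
  for (sub in grep("^nest_", names(tab), value = TRUE)) {
    w <- suppressWarnings(as.numeric(taxon[[sub]]))
    if (is.na(w) || w == 0) next
    hn <- pmax(hn, matrix(tab[[sub]][idx], nr) * w)
  }
  hf <- matrix(tab[[paste0("floral_", season)]][idx], nr)
  alpha <- as.numeric(taxon$alpha_m)
  act <- as.numeric(taxon[[paste0("activity_", season)]])
  p <- hn * oracle_favg(hf, alpha, lulc$grid$resolution, cutoff)
  oracle_favg(p, alpha, lulc$grid$resolution, cutoff) * act
}

# brute-force % natural cover within a circular window (counting oracle)
oracle_cover <- function(mask, radius_m, res) {
  nr <- nrow(mask); nc <- ncol(mask)
  rmax <- ceiling(radius_m / res)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    hit <- 0; tot <- 0
    for (rr in max(1, r - rmax):min(nr, r + rmax)) {
      for (cc in max(1, c - rmax):min(nc, c + rmax)) {
        if (sqrt((rr - r)^2 + (cc - c)^2) * res <= radius_m) {
          tot <- tot + 1
          hit <- hit + mask[rr, cc]
        }
      }
    }
    out[r, c] <- 100 * hit / tot
  }
  out
}

# independent connected-component labelling via igraph
oracle_filter_patches <- function(mask, min_area_ha, cell_ha, connectivity = 8) {
  idx <- which(mask > 0)
  if (!length(idx)) return(mask * 0)
  nr <- nrow(mask)
  r <- ((idx - 1) %% nr) + 1; c <- ((idx - 1) %/% nr) + 1
  edges <- integer(0)
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i >= j) next
    dr <- abs(r[i] - r[j]); dc <- abs(c[i] - c[j])
    ok <- if (connectivity == 8) max(dr, dc) == 1 else dr + dc == 1
    if (ok) edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- comp$csize[comp$membership] * cell_ha >= min_area_ha
  out <- mask * 0
  out[idx[keep]] <- 1
  out
}
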