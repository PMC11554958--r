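#' Detect abandoned crop fields from cultivation histories
#'
#' A field counts as abandoned when it was not cultivated in any of the
#' final `window` consecutive years of its history (cessation of farming
#' for at least five years in the reference setup, which also guards
#' against flagging ordinary fallow). Fields whose map cells are already
#' dominated by a natural class (old field / shrubland regrowth) are
#' excluded when a LULC map is supplied, since those are already habitat.
#'
#' @param registry a [field_registry()].
#' @param window number of terminal uncultivated years required (default 5).
#' @param lulc optional `bs_lulc` used for the natural-regrowth exclusion.
#' @param labels optional field-label raster (required with `lulc`).
#' @return sorted integer vector of abandoned field ids.
#' @export
detect_abandoned <- function(registry, window = 5, lulc = NULL, labels = NULL) {
  yrs <- registry$years
  term <- yrs[(length(yrs) - window + 1):length(yrs)]
  h <- registry$history
  out <- integer(0)
  for (id in registry$fields$field_id) {
    sub <- h[h$field_id == id & h$year %in% term, ]
    if (nrow(sub) < window)
      stop("field ", id, " is missing years inside the abandonment window")
    if (!any(sub$cultivated)) out <- c(out, id)
  }
  if (!is.null(lulc) && length(out)) {
    if (is.null(labels)) labels <- rasterize_fields(registry, lulc$grid)
    nat <- class_row(lulc, "is_natural")
    keep <- vapply(out, function(id) {
      cells <- labels == id
      !any(cells) || mean(nat[cells]) <= 0.5
    }, logical(1))
    out <- out[keep]
  }
  sort(out)
}

#' Pixel-wise linear NDVI trend
#'
#' Ordinary least squares of annual NDVI on year index for every cell in
#' the mask; the two-sided p-value comes from the t statistic on n-2
#' degrees of freedom. A zero-variance (perfectly constant) series gets
#' slope 0 and p = 1 so that pristine fields are never flagged; a perfect
#' non-constant line gets p = 0.
#'
#' @param ndvi 3-d array (rows, cols, years) or the `ndvi` element of a
#'   bundle.
#' @param mask logical matrix of cells to fit (default: all).
#' @return list of matrices `slope`, `p_value`, plus `n_years`; cells
#'   outside the mask are NA.
#' @export
fit_ndvi_trend <- function(ndvi, mask = NULL) {
  if (is.list(ndvi)) ndvi <- ndvi$values
  d <- dim(ndvi)
  n <- d[3]
  if (n < 3) stop("trend fitting needs >= 3 years")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  x <- seq_len(n) - 1
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  flat <- matrix(ndvi, nrow = d[1] * d[2], ncol = n)
  keep <- as.vector(mask) & rowSums(is.na(flat)) == 0
  slope <- p <- rep(NA_real_, d[1] * d[2])
  if (any(keep)) {
    y <- flat[keep, , drop = FALSE]
    b1 <- as.vector(y %*% xc) / sxx
    b0 <- rowMeans(y) - b1 * mean(x)
    resid <- y - outer(b0, rep(1, n)) - outer(b1, x)
    rss <- rowSums(resid^2)
    se <- sqrt(rss / (n - 2) / sxx)
    pv <- ifelse(se > 0, 2 * stats::pt(-abs(b1 / se), df = n - 2),
                 ifelse(b1 == 0, 1, 0))
    # residual-free fits, up to floating-point noise: a constant series is
    # never significant (p = 1), a perfect sloped line always is (p = 0)
    yscale <- rowMeans(abs(y)) + 1e-300
    perfect <- sqrt(rss / (n - 2)) < 1e-10 * yscale
    pv[perfect] <- ifelse(abs(b1[perfect]) < 1e-10 * yscale[perfect], 1, 0)
    slope[keep] <- b1
    p[keep] <- pv
  }
  list(slope = matrix(slope, d[1]), p_value = matrix(p, d[1]), n_years = n)
}

# 8-neighbour erosion of each labelled field by one cell ring: a cell
# survives when all neighbours (including diagonals) carry the same label.
erode_labels <- function(labels, cells = 1) {
  keep <- labels > 0
  for (k in seq_len(cells)) {
    nr <- nrow(labels); nc <- ncol(labels)
    pad <- matrix(-1L, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- labels
    padk <- matrix(FALSE, nr + 2, nc + 2)
    padk[2:(nr + 1), 2:(nc + 1)] <- keep
    ok <- keep
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      same <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)] == labels
      there <- padk[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
      ok <- ok & same & there
    }
    keep <- ok
    labels[!keep] <- 0L
  }
  keep
}

#' Degraded-pixel mask from NDVI trends
#'
#' A cell is flagged when its NDVI slope is negative with p <= `p_max` and
#' it survives erosion of `erosion_m` inward from its field boundary (25 m
#' is one cell ring at 30-m resolution), which removes pixels contaminated
#' by edges (roads, hedges, soil margins).
#'
#' @param trend result of [fit_ndvi_trend()].
#' @param labels field-label raster from [rasterize_fields()].
#' @param p_max significance threshold on the trend (default 0.05).
#' @param erosion_m edge-removal width in m (default 25); converted to
#'   whole cell rings by ceiling at the raster resolution.
#' @param resolution_m cell size in m (default 30).
#' @return 0/1 matrix.
#' @export
degraded_pixel_mask <- function(trend, labels, p_max = 0.05, erosion_m = 25,
                                resolution_m = 30) {
  rings <- max(1L, as.integer(ceiling(erosion_m / resolution_m)))
  interior <- erode_labels(labels, cells = rings)
  flag <- !is.na(trend$slope) & trend$slope < 0 &
    !is.na(trend$p_value) & trend$p_value <= p_max
  (flag & interior) * 1
}

# Connected-component labelling by breadth-first flood fill.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  cur <- 0L
  todo <- which(mask > 0)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cell - 1) %% nr) + 1; c <- ((cell - 1) %/% nr) + 1
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        idx <- (cc - 1) * nr + rr
        if (mask[idx] > 0 && lab[idx] == 0L) {
          lab[idx] <- cur
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}

#' Remove small patches from a binary raster
#'
#' Connected components (8-neighbour by default) smaller than
#' `min_area_ha` are dropped: restoring scattered sub-0.15-ha slivers
#' inside working fields is impractical for machinery, so only coherent
#' degraded patches count.
#'
#' @param mask 0/1 matrix.
#' @param min_area_ha minimum patch area kept (default 0.15).
#' @param cell_ha area of one cell in ha (default 0.09 for 30-m cells).
#' @param connectivity 4 or 8 (default 8).
#' @return filtered 0/1 matrix.
#' @export
filter_patches <- function(mask, min_area_ha = 0.15, cell_ha = 0.09,
                           connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (!max(lab)) return(mask * 0)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes * cell_ha < min_area_ha)
  out <- mask
  out[lab %in% small] <- 0
  out * 1
}

#' Classify entire fields as degraded
#'
#' A field is degraded when the filtered degraded-pixel patches cover at
#' least `fraction` (default 30%) of its *full* pre-erosion area, in which
#' case the whole field is treated as potentially degraded; otherwise the
#' field is non-degraded and its flagged pixels contribute nothing
#' downstream.
#'
#' @param mask filtered 0/1 degraded-pixel raster.
#' @param labels field-label raster.
#' @param registry a [field_registry()].
#' @param fraction area-fraction threshold (default 0.30, boundary
#'   inclusive).
#' @param cell_ha cell area in ha (default 0.09).
#' @return sorted integer vector of degraded field ids.
#' @export
classify_degraded_fields <- function(mask, labels, registry, fraction = 0.30,
                                     cell_ha = 0.09) {
  flagged <- labels[mask > 0]
  flagged <- flagged[flagged > 0]
  if (!length(flagged)) return(integer(0))
  counts <- table(flagged)
  ids <- as.integer(names(counts))
  area_flagged <- as.numeric(counts) * cell_ha
  field_area <- registry$fields$area_ha[match(ids, registry$fields$field_id)]
  sort(ids[area_flagged / field_area >= fraction - 1e-12])
}

#' Full marginal-land report for a landscape
#'
#' Runs abandonment detection and the NDVI degradation pipeline (trend fit,
#' edge erosion, significance filter, patch filter, 30% field rule) and
#' totals the areas.
#'
#' @param bundle a `bs_bundle`, or pass `registry`, `labels`, `ndvi`,
#'   `lulc` individually.
#' @param window,p_max,min_patch_ha,fraction,erosion_m stage parameters
#'   (defaults: 5 yr, 0.05, 0.15 ha, 0.30, 25 m).
#' @param registry,labels,ndvi,lulc individual inputs overriding `bundle`.
#' @return a `bs_marginal` list: `abandoned_ids`, `degraded_ids`,
#'   `marginal_ids` (union), `degraded_pixel_mask`, `total_abandoned_ha`,
#'   `total_degraded_ha`, `total_marginal_ha`.
#' @export
marginal_report <- function(bundle = NULL, window = 5, p_max = 0.05,
                            min_patch_ha = 0.15, fraction = 0.30,
                            erosion_m = 25,
                            registry = bundle$registry, labels = bundle$labels,
                            ndvi = bundle$ndvi, lulc = bundle$lulc) {
  if (is.null(labels)) labels <- rasterize_fields(registry, lulc$grid)
  abandoned <- detect_abandoned(registry, window = window, lulc = lulc,
                                labels = labels)
  trend <- fit_ndvi_trend(ndvi, mask = labels > 0)
  cell_ha <- cell_area_ha(lulc$grid)
  mask <- degraded_pixel_mask(trend, labels, p_max = p_max,
                              erosion_m = erosion_m,
                              resolution_m = lulc$grid$resolution)
  mask <- filter_patches(mask, min_area_ha = min_patch_ha, cell_ha = cell_ha)
  degraded <- classify_degraded_fields(mask, labels, registry,
                                       fraction = fraction, cell_ha = cell_ha)
  # fields failing the 30% rule contribute nothing downstream
  mask[!(labels %in% degraded)] <- 0
  fa <- registry$fields
  marg <- sort(union(abandoned, degraded))
  structure(list(abandoned_ids = abandoned, degraded_ids = degraded,
                 marginal_ids = marg,
                 degraded_pixel_mask = mask,
                 total_abandoned_ha = sum(fa$area_ha[fa$field_id %in% abandoned]),
                 total_degraded_ha = sum(fa$area_ha[fa$field_id %in% degraded]),
                 total_marginal_ha = sum(fa$area_ha[fa$field_id %in% marg])),
            class = "bs_marginal")
}

#' @export
print.bs_marginal <- function(x, ...) {
  cat(sprintf("<bs_marginal> %d abandoned (%.1f ha), %d degraded (%.1f ha), union %.1f ha\n",
              length(x$abandoned_ids), x$total_abandoned_ha,
              length(x$degraded_ids), x$total_degraded_ha, x$total_marginal_ha))
  invisible(x)
}
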