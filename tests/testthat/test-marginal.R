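make_history <- function(cultivated, years = 2012:2021, id = 1) {
  data.frame(field_id = id, year = years, cultivated = cultivated,
             crop_code = ifelse(cultivated, "corn", NA), stringsAsFactors = FALSE)
}

one_field_registry <- function(cultivated) {
  poly <- rect_polygon(0, 0, 300, 300)
  field_registry(list(`1` = poly), make_history(cultivated))
}

test_that("abandonment requires a terminal uncultivated window", {
  always <- one_field_registry(rep(TRUE, 10))
  expect_length(detect_abandoned(always), 0)

  idle5 <- one_field_registry(c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(detect_abandoned(idle5), 1L)

  # idle 5 years but cultivated again in the final year: not abandoned
  resumed <- one_field_registry(c(rep(TRUE, 4), rep(FALSE, 5), TRUE))
  expect_length(detect_abandoned(resumed), 0)
})

test_that("abandonment ignores history before the terminal window", {
  a <- one_field_registry(c(rep(TRUE, 5), rep(FALSE, 5)))
  b <- one_field_registry(c(rep(FALSE, 5), rep(FALSE, 5)))
  expect_identical(detect_abandoned(a), detect_abandoned(b))
})

test_that("fields already under woody regrowth in the LULC are excluded", {
  b <- small_bundle()
  id <- b$truth$abandoned[1]
  regrown <- reclassify(b$lulc, b$labels == id, 6)   # oldfield_shrubland
  det <- detect_abandoned(b$registry, lulc = regrown, labels = b$labels)
  expect_false(id %in% det)
  expect_setequal(det, setdiff(b$truth$abandoned, id))
})

test_that("pixel-wise NDVI regression matches lm and handles degenerate series", {
  arr <- array(0, c(1, 3, 5))
  arr[1, 1, ] <- c(0.8, 0.7, 0.6, 0.5, 0.4)      # perfect decline
  arr[1, 2, ] <- 0.7                              # constant
  arr[1, 3, ] <- c(0.8, 0.75, 0.78, 0.7, 0.72)   # noisy
  tr <- fit_ndvi_trend(arr)
  expect_equal(tr$slope[1, 1], -0.1, tolerance = 1e-12)
  expect_lt(tr$p_value[1, 1], 1e-6)
  expect_equal(tr$slope[1, 2], 0)
  expect_equal(tr$p_value[1, 2], 1)               # zero-variance convention
  fit <- stats::lm(arr[1, 3, ] ~ I(0:4))
  expect_equal(tr$slope[1, 3], unname(stats::coef(fit)[2]), tolerance = 1e-10)
  expect_equal(tr$p_value[1, 3],
               summary(fit)$coefficients[2, 4], tolerance = 1e-10)
})

test_that("degraded pixels need a significant negative trend and edge erosion", {
  lab <- matrix(0L, 5, 5); lab[2:4, 2:4] <- 1L    # a 3x3-cell field
  slope <- matrix(-0.01, 5, 5)
  p <- matrix(0.04, 5, 5)
  m <- degraded_pixel_mask(list(slope = slope, p_value = p), lab)
  expect_equal(which(m == 1), 13L)                # only the center survives
  p[3, 3] <- 0.06                                 # fails the p cutoff
  m2 <- degraded_pixel_mask(list(slope = slope, p_value = p), lab)
  expect_true(all(m2 == 0))
  p[3, 3] <- 0.05                                 # boundary inclusive
  slope[3, 3] <- 0.01                             # positive trend never flags
  m3 <- degraded_pixel_mask(list(slope = slope, p_value = p), lab)
  expect_true(all(m3 == 0))
})

test_that("patch filtering matches an independent component-labelling oracle", {
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  expect_true(all(filter_patches(one) == 0))      # 0.09 ha < 0.15 ha

  diag2 <- matrix(0, 5, 5); diag2[2, 2] <- 1; diag2[3, 3] <- 1
  expect_equal(sum(filter_patches(diag2)), 2)     # 0.18 ha, 8-connected
  expect_true(all(filter_patches(diag2, connectivity = 4) == 0))

  set.seed(11)
  for (k in 1:5) {
    m <- matrix(rbinom(100, 1, 0.3), 10, 10)
    for (conn in c(4, 8)) {
      got <- filter_patches(m, min_area_ha = 0.2, cell_ha = 0.09,
                            connectivity = conn)
      want <- oracle_filter_patches(m, 0.2, 0.09, connectivity = conn)
      expect_identical(got, want)
    }
  }
})

test_that("the 30% field rule is inclusive at the boundary", {
  g <- landscape_grid(6, 12, resolution = 30)
  reg <- rect_field_registry(g, 2, 2, 1, 10)      # 10 cells = 0.9 ha
  lab <- rasterize_fields(reg, g)
  m <- matrix(0, 6, 12); m[2, 2:4] <- 1           # 3 flagged cells: 30%
  expect_equal(classify_degraded_fields(m, lab, reg), 1L)
  m[2, 4] <- 0                                    # 2 cells: 20%
  expect_length(classify_degraded_fields(m, lab, reg), 0)
})

test_that("detection recovers planted ground truth on a synthetic landscape", {
  b <- small_bundle()
  rep <- marginal_report(b)
  expect_identical(rep$abandoned_ids, as.integer(b$truth$abandoned))
  expect_true(all(b$truth$degraded %in% rep$degraded_ids))
  fa <- b$registry$fields
  expect_equal(rep$total_abandoned_ha,
               sum(fa$area_ha[fa$field_id %in% rep$abandoned_ids]))
  expect_equal(rep$total_marginal_ha,
               sum(fa$area_ha[fa$field_id %in% union(rep$abandoned_ids,
                                                     rep$degraded_ids)]))
})

test_that("tightening thresholds never adds degraded fields", {
  b <- small_bundle()
  trend <- fit_ndvi_trend(b$ndvi, mask = b$labels > 0)
  base_mask <- degraded_pixel_mask(trend, b$labels, p_max = 0.05)
  strict_mask <- degraded_pixel_mask(trend, b$labels, p_max = 0.01)
  cell_ha <- cell_area_ha(b$lulc$grid)
  base <- classify_degraded_fields(
    filter_patches(base_mask, 0.15, cell_ha), b$labels, b$registry)
  stricter_p <- classify_degraded_fields(
    filter_patches(strict_mask, 0.15, cell_ha), b$labels, b$registry)
  bigger_patch <- classify_degraded_fields(
    filter_patches(base_mask, 0.45, cell_ha), b$labels, b$registry)
  expect_true(all(stricter_p %in% base))
  expect_true(all(bigger_patch %in% base))
})
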