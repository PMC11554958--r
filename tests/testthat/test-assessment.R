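test_that("min-max scaling spans [0, 1] with the constant-raster convention", {
  m <- matrix(c(2, 4, 6), 1)
  expect_equal(minmax_scale(m), matrix(c(0, 0.5, 1), 1))
  expect_equal(minmax_scale(matrix(5, 3, 3)), matrix(0, 3, 3))
  set.seed(2)
  r <- matrix(rnorm(100), 10)
  expect_equal(range(minmax_scale(r)), c(0, 1))
})

test_that("tertile classification uses interpolated sample quantiles", {
  cls <- tertile_classify(1:9)
  expect_equal(as.character(cls),
               rep(c("low", "intermediate", "high"), each = 3))
  expect_warning(all_eq <- tertile_classify(rep(4, 5)), "distinct")
  expect_true(all(all_eq == "low"))                  # q1 = q2 = value
  three <- tertile_classify(c(0, 0, 0, 5, 5, 5, 9, 9, 9))
  expect_equal(as.integer(table(three)), c(3, 3, 3))
})

test_that("the bivariate matrix balances mass and finds demand hotspots", {
  # 9 fields, one per supply x demand combination, equal areas
  sup <- rep(1:3, times = 3); dem <- rep(1:3, each = 3)
  bv <- bivariate_matrix(sup, dem, rep(10, 9), field_id = 1:9)
  expect_equal(as.vector(bv$matrix), rep(100 / 9, 9), tolerance = 1e-9)
  expect_equal(sum(bv$matrix), 100, tolerance = 0.1)
  # hotspots: low supply with intermediate/high demand
  expect_setequal(bv$hotspot_ids,
                  which(sup == 1 & dem >= 2))
  # rank-based: any strictly monotone transform leaves the result unchanged
  bv2 <- bivariate_matrix(exp(sup), dem^3 + 1, rep(10, 9), field_id = 1:9)
  expect_identical(bv2$fields$supply_tertile, bv$fields$supply_tertile)
  expect_identical(bv2$hotspot_ids, bv$hotspot_ids)

  # identical rank orders concentrate mass on the diagonal
  set.seed(8)
  v <- runif(30)
  bd <- bivariate_matrix(v, 2 * v, rep(1, 30))
  expect_equal(sum(diag(bd$matrix)), 100, tolerance = 1e-9)
})

test_that("focal natural cover matches the counting oracle", {
  expect_true(all(natural_cover_pct(matrix(1, 8, 8), 60, 30) == 100))
  expect_true(all(natural_cover_pct(matrix(0, 8, 8), 60, 30) == 0))

  # half-plane forest: boundary cells sit near 50%
  hp <- matrix(0, 20, 20); hp[, 1:10] <- 1
  cov <- natural_cover_pct(hp, 150, 30)
  expect_equal(cov[10, 10], 50, tolerance = 6)
  expect_equal(cov[10, 11], 50, tolerance = 6)
  expect_equal(cov[10, 10] + cov[10, 11], 100, tolerance = 1e-6)

  set.seed(13)
  m <- matrix(rbinom(400, 1, 0.3), 20, 20)
  expect_equal(natural_cover_pct(m, 100, 30), oracle_cover(m, 100, 30),
               tolerance = 1e-9)
})

test_that("field-centroid cover is the mean of the window cells", {
  g <- landscape_grid(20, 20, resolution = 30)
  cst <- matrix(37, 20, 20)
  expect_equal(field_natural_cover(cst, g, 300, 300, radius_m = 150), 37)
  set.seed(21)
  cov <- matrix(runif(400, 0, 100), 20, 20)
  got <- field_natural_cover(cov, g, 310, 295, radius_m = 120)
  # double-loop oracle
  cx <- cell_centers_x(g); cy <- cell_centers_y(g)
  acc <- c()
  for (r in 1:20) for (c in 1:20)
    if ((cx[c] - 310)^2 + (cy[r] - 295)^2 <= 120^2) acc <- c(acc, cov[r, c])
  expect_equal(got, mean(acc), tolerance = 1e-9)
})

test_that("priority ranking respects the 5/10/20 boundaries and sums to 100", {
  pr <- priority_ranking(c(4.9, 5, 9.99, 10, 19.9, 20), rep(1, 6))
  expect_equal(as.character(pr$fields$category),
               c("high", "intermediate", "intermediate", "low", "low", "none"))
  expect_equal(sum(pr$summary$pct), 100, tolerance = 0.1)

  pr2 <- priority_ranking(c(3, 12, 25), rep(10, 3), ag_zone_ha = 30)
  expect_equal(pr2$summary$pct, c(100 / 3, 0, 100 / 3, 100 / 3), tolerance = 1e-9)
})

test_that("the S/D ratio is defined only where raw demand is positive", {
  sup <- matrix(c(0.5, 0, 0.8), 1)
  dem_raster <- matrix(c(1, 2, 0), 1)
  dem <- list(raster = dem_raster, normalized = minmax_scale(dem_raster))
  sd <- sd_ratio(sup, dem)
  expect_equal(sd[1, 1], 0.5 / 0.5)
  expect_equal(sd[1, 2], 0)                       # zero supply, demand > 0
  expect_true(is.na(sd[1, 3]))                    # no demand: undefined
})

test_that("1-km aggregation retains agricultural blocks and counts S/D >= 1", {
  g <- landscape_grid(100, 100, resolution = 30)   # 3 x 3 km, no buffer
  lulc <- lulc_map(g, matrix(1, 100, 100), default_class_table(), buffer_m = 0)
  ag <- matrix(TRUE, 100, 100)
  up <- aggregate_sd(matrix(1.2, 100, 100), lulc, ag)
  expect_equal(up$pct_ge1, 100)
  down <- aggregate_sd(matrix(0.8, 100, 100), lulc, ag)
  expect_equal(down$pct_ge1, 0)

  # checkerboard of 1-km blocks alternating 0.5 and 1.5
  per <- 1000 / 30
  block_id <- outer(0:99, 0:99, function(r, c)
    (floor(r / per) + floor(c / per)) %% 2)
  sd <- matrix(0.5, 100, 100); sd[block_id == 1] <- 1.5
  half <- aggregate_sd(sd, lulc, ag)
  # 3 x 3 blocks of alternating parity: 4 of the 9 sit at 1.5
  expect_equal(half$pct_ge1, 400 / 9, tolerance = 1e-9)

  # blocks with too little agriculture are dropped
  ag2 <- ag; ag2[, 1:50] <- FALSE
  part <- aggregate_sd(matrix(1.2, 100, 100), lulc, ag2)
  expect_lt(part$n_retained, up$n_retained)
  expect_error(aggregate_sd(matrix(1, 100, 100), lulc,
                            matrix(FALSE, 100, 100)), "retained")
})

test_that("the S/D >= 1 share is invariant to rescaling raw demand weights", {
  b <- small_bundle()
  reg <- set_marginal_flags(b$registry, abandoned = b$truth$abandoned,
                            degraded = b$truth$degraded)
  core <- core_mask(b$lulc)
  d1 <- demand_map(reg, b$lulc$grid, labels = b$labels, core = core)
  d3 <- d1
  d3$raster <- 3 * d1$raster                      # x3 all dependency weights
  d3$normalized <- minmax_scale(d3$raster, core)
  sup <- minmax_scale(matrix(seq_len(length(b$labels)), nrow(b$labels)), core)
  ag <- agricultural_mask(b$lulc, b$labels)
  a1 <- aggregate_sd(sd_ratio(sup, d1), b$lulc, ag)
  a3 <- aggregate_sd(sd_ratio(sup, d3), b$lulc, ag)
  expect_equal(a1$pct_ge1, a3$pct_ge1, tolerance = 1e-9)
})

test_that("comparing a baseline against itself gives zero deltas", {
  mk <- function(nm, pct) {
    structure(list(scenario_name = nm,
                   ledger = list(reforested_ha = 0, strips_ha = 0, restored_ha = 0),
                   restored_fraction = 0, pct_sd_ge1 = pct,
                   bivariate = list(hotspot_pct = 10),
                   priority = list(summary = data.frame(
                     category = factor(c("high", "intermediate", "low", "none")),
                     total_ha = 1, pct = 25))),
              class = "bs_assessment")
  }
  cmp <- compare_scenarios(list(mk("no_restoration", 30), mk("other", 42)))
  expect_equal(cmp$delta_pct_sd_ge1, c(0, 12))
  expect_error(compare_scenarios(list(mk("other", 42))), "baseline")
})
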