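# 16x16-cell toy landscape (no buffer) with four aligned rectangular fields
toy_landscape <- function(abandoned = integer(0)) {
  g <- landscape_grid(16, 16, resolution = 30)
  polys <- list(`1` = rect_polygon(30, 300, 330, 390),    # 300 x 90 m
                `2` = rect_polygon(30, 120, 330, 210),
                `3` = rect_polygon(360, 300, 450, 390),
                `4` = rect_polygon(360, 60, 450, 150))
  hist <- do.call(rbind, lapply(1:4, function(id)
    data.frame(field_id = id, year = 2012:2021,
               cultivated = !(id %in% abandoned & TRUE),
               crop_code = ifelse(id %in% abandoned, NA, "canola"))))
  reg <- field_registry(polys, hist, abandoned = abandoned)
  codes <- matrix(4, 16, 16)
  lulc <- lulc_map(g, codes, default_class_table(), buffer_m = 0)
  lab <- rasterize_fields(reg, g)
  lulc <- reclassify(lulc, lab > 0, 2)
  list(lulc = lulc, registry = reg, labels = lab, grid = g)
}

toy_report <- function(registry, abandoned = integer(0), degraded = integer(0)) {
  fa <- registry$fields
  marg <- sort(union(abandoned, degraded))
  structure(list(abandoned_ids = abandoned, degraded_ids = degraded,
                 marginal_ids = marg,
                 degraded_pixel_mask = NULL,
                 total_abandoned_ha = sum(fa$area_ha[fa$field_id %in% abandoned]),
                 total_degraded_ha = sum(fa$area_ha[fa$field_id %in% degraded]),
                 total_marginal_ha = sum(fa$area_ha[fa$field_id %in% marg])),
            class = "bs_marginal")
}

test_that("longest_edge picks the longest segment with ring-order tie-breaks", {
  r <- rect_polygon(0, 0, 600, 100)
  e <- longest_edge(r)
  expect_equal(sqrt(sum((e[2, ] - e[1, ])^2)), 600)

  sq <- rect_polygon(0, 0, 100, 100)
  esq <- longest_edge(sq)                       # first edge in ring order
  expect_equal(unname(esq[1, ]), c(0, 0))
  expect_equal(unname(esq[2, ]), c(100, 0))

  # L-shape with edge lengths (300, 200, 150, 100, 150, 300): first 300 wins
  L <- cbind(x = c(0, 300, 300, 150, 150, 0),
             y = c(0, 0, 200, 200, 300, 300))
  eL <- longest_edge(L)
  expect_equal(unname(eL[1, ]), c(0, 0))
  expect_equal(unname(eL[2, ]), c(300, 0))
  expect_error(longest_edge(cbind(c(0, 1), c(0, 1))), "degenerate")
})

test_that("flower strips hug the longest edge with vector-exact areas", {
  s <- build_flower_strip(rect_polygon(0, 0, 600, 100), field_id = 1)
  expect_equal(s$area_ha, 0.30, tolerance = 1e-9)      # 600 m x 5 m
  s2 <- build_flower_strip(rect_polygon(0, 0, 100, 100))
  expect_equal(s2$area_ha, 0.05, tolerance = 1e-9)

  # convex irregular field: strip stays inside and below the edge bound
  tri <- cbind(x = c(0, 400, 120), y = c(0, 0, 350))
  st <- build_flower_strip(tri, field_id = 9)
  edge_len <- sqrt(sum((st$edge[2, ] - st$edge[1, ])^2))
  expect_lte(st$area_ha, 5 * edge_len / 1e4 + 1e-9)
  pts <- st$polygon
  mid <- (pts + pts[c(2:nrow(pts), 1), ]) / 2          # edge midpoints
  shrink <- function(p) {
    ctr <- polygon_centroid(st$polygon)
    cbind((p[, 1] - ctr[1]) * (1 - 1e-9) + ctr[1],
          (p[, 2] - ctr[2]) * (1 - 1e-9) + ctr[2])
  }
  inside <- shrink(rbind(pts, mid))
  expect_true(all(point_in_polygon(inside[, 1], inside[, 2], tri)))
})

test_that("reforestation converts exactly the marginal fields", {
  tl <- toy_landscape()
  rep0 <- toy_report(tl$registry)
  s0 <- scenario_reforest_marginal(tl$lulc, tl$registry, rep0, labels = tl$labels)
  expect_identical(s0$lulc$codes, tl$lulc$codes)       # nothing marginal
  expect_equal(s0$ledger$restored_ha, 0)

  tl2 <- toy_landscape(abandoned = 1)
  rep1 <- toy_report(tl2$registry, abandoned = 1)
  s1 <- scenario_reforest_marginal(tl2$lulc, tl2$registry, rep1, labels = tl2$labels)
  expect_equal(s1$ledger$reforested_ha, 2.7)           # 300 x 90 m
  expect_equal(sum(s1$lulc$codes == 4) - sum(tl2$lulc$codes == 4),
               sum(tl2$labels == 1))
  # grid extent and class table conserved
  expect_identical(dim(s1$lulc$codes), dim(tl2$lulc$codes))
  expect_identical(s1$lulc$class_table, tl2$lulc$class_table)
})

test_that("flower-strip scenario covers every non-marginal field, additively", {
  tl <- toy_landscape(abandoned = 1)
  rep1 <- toy_report(tl$registry, abandoned = 1)
  s <- scenario_flower_strips(tl$lulc, tl$registry, rep1, labels = tl$labels)
  expect_length(s$strips, 3)
  per_strip <- vapply(s$strips, `[[`, numeric(1), "area_ha")
  expect_equal(s$ledger$strips_ha, sum(per_strip))
  expect_equal(per_strip[1], 300 * 5 / 1e4, tolerance = 1e-9)  # fields 1-2: 300-m edges
  # all fields marginal -> no strips
  repall <- toy_report(tl$registry, abandoned = 1:4)
  sall <- scenario_flower_strips(tl$lulc, tl$registry, repall, labels = tl$labels)
  expect_length(sall$strips, 0)
  expect_identical(sall$lulc$codes, tl$lulc$codes)
  # strip cells are burned to the flower-strip class inside their own field
  expect_true(all(tl$labels[s$lulc$codes == 11] %in% c(2, 3, 4)))
})

test_that("the mixed strategy removes the strips closest to future forest first", {
  tl <- toy_landscape(abandoned = 1)
  rep1 <- toy_report(tl$registry, abandoned = 1)
  # field 2 is 90 m from field 1; field 3 is 30 m away; field 4 is 150 m.
  # Priority buffer centered on field 2 covers everything (radius 1 km).
  cover <- stats::setNames(rep(1, 4), 1:4)             # all "simplified"
  all_strips <- scenario_flower_strips(tl$lulc, tl$registry, rep1,
                                       labels = tl$labels)
  strip_ha <- vapply(all_strips$strips, `[[`, numeric(1), "area_ha")
  total <- rep1$total_marginal_ha + sum(strip_ha)
  terr <- territory_ha(tl$lulc)

  # target admits all candidates -> nothing removed
  s_all <- scenario_mixed(tl$lulc, tl$registry, rep1, hotspot_ids = 2L,
                          field_cover = cover, labels = tl$labels,
                          target_fraction = total / terr + 0.01)
  expect_length(s_all$strips, 3)

  # target forces exactly one removal -> the strip nearest field 1 goes
  target1 <- (total - min(strip_ha) / 2) / terr
  s_one <- scenario_mixed(tl$lulc, tl$registry, rep1, hotspot_ids = 2L,
                          field_cover = cover, labels = tl$labels,
                          target_fraction = target1)
  expect_length(s_one$strips, 2)
  dropped <- setdiff(vapply(all_strips$strips, `[[`, numeric(1), "field_id"),
                     vapply(s_one$strips, `[[`, numeric(1), "field_id"))
  d <- vapply(c(2, 3, 4), function(id)
    polygon_distance(tl$registry$polygons[["1"]],
                     tl$registry$polygons[[as.character(id)]]), numeric(1))
  expect_equal(dropped, c(2, 3, 4)[which.min(d)])
  expect_lte(s_one$ledger$restored_ha, target1 * terr + 1e-9)

  # no priority fields -> identity with a warning
  expect_warning(
    s_none <- scenario_mixed(tl$lulc, tl$registry, rep1, hotspot_ids = integer(0),
                             field_cover = cover, labels = tl$labels),
    "no priority")
  expect_identical(s_none$lulc$codes, tl$lulc$codes)
})

test_that("maximal restoration excludes strips within 50 m of marginal fields", {
  tl <- toy_landscape(abandoned = 1)
  rep1 <- toy_report(tl$registry, abandoned = 1)
  s <- scenario_maximal(tl$lulc, tl$registry, rep1, labels = tl$labels)
  with_strip <- vapply(s$strips, `[[`, numeric(1), "field_id")
  # field 3 is 30 m from field 1 -> excluded; fields 2 (90 m) and 4 keep strips
  expect_setequal(with_strip, c(2, 4))
  expect_equal(s$ledger$reforested_ha, rep1$total_marginal_ha)

  # no marginal fields -> identical to the flower-strips scenario
  rep0 <- toy_report(tl$registry)
  smax <- scenario_maximal(tl$lulc, tl$registry, rep0, labels = tl$labels)
  sstr <- scenario_flower_strips(tl$lulc, tl$registry, rep0, labels = tl$labels)
  expect_equal(smax$ledger$strips_ha, sstr$ledger$strips_ha)
  expect_identical(smax$lulc$codes, sstr$lulc$codes)
})

test_that("ledger fractions are vector-accounted against the territory", {
  tl <- toy_landscape(abandoned = 1)
  rep1 <- toy_report(tl$registry, abandoned = 1)
  s <- scenario_maximal(tl$lulc, tl$registry, rep1, labels = tl$labels)
  expect_equal(s$restored_fraction,
               (s$ledger$reforested_ha + s$ledger$strips_ha) / territory_ha(tl$lulc))
  # strips never touch marginal fields
  for (st in s$strips)
    expect_gt(polygon_distance(st$polygon, tl$registry$polygons[["1"]]), 0)
})
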