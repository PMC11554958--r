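test_that("grid geometry follows the row-0-north convention", {
  g <- landscape_grid(4, 5, resolution = 30, origin_x = 100, origin_y = 400)
  expect_equal(cell_centers_x(g)[1], 115)
  expect_equal(cell_centers_y(g)[1], 385)   # row 1 is northernmost
  expect_equal(cell_area_ha(g), 0.09)
  ci <- cell_index(g, c(115, 100 + 5 * 30 - 1, 99), c(385, 400 - 4 * 30 + 1, 385))
  expect_equal(ci$row, c(1L, 4L, NA))
  expect_equal(ci$col, c(1L, 5L, NA))
})

test_that("rasterization by cell-center containment is exact for aligned fields", {
  g <- landscape_grid(20, 20, resolution = 30)
  # one 300 m x 300 m square aligned to the grid: 9 ha / 0.09 ha = 100 cells
  reg <- rect_field_registry(g, r0 = 3, c0 = 4, nr = 10, nc = 10)
  lab <- rasterize_fields(reg, g)
  expect_equal(sum(lab == 1), 100)
  expect_equal(reg$fields$area_ha, 9, tolerance = 1e-9)

  # empty registry -> all-zero raster
  empty <- field_registry(list(),
                          data.frame(field_id = integer(0), year = integer(0),
                                     cultivated = logical(0),
                                     crop_code = character(0)))
  expect_true(all(rasterize_fields(empty, g) == 0))
})

test_that("adjacent fields get disjoint labels equal to the center-containment oracle", {
  g <- landscape_grid(12, 12, resolution = 30)
  polys <- list(`1` = rect_polygon(30, 30, 150, 330),
                `2` = rect_polygon(150, 30, 300, 330))
  hist <- data.frame(field_id = rep(1:2, each = 3), year = rep(2019:2021, 2),
                     cultivated = TRUE, crop_code = "corn")
  reg <- field_registry(polys, hist)
  lab <- rasterize_fields(reg, g)
  cx <- cell_centers_x(g); cy <- cell_centers_y(g)
  for (r in 1:12) for (c in 1:12) {
    in1 <- point_in_polygon(cx[c], cy[r], polys$`1`)
    in2 <- point_in_polygon(cx[c], cy[r], polys$`2`)
    expect_false(in1 && in2)
    expect_equal(lab[r, c], if (in1) 1L else if (in2) 2L else 0L)
  }
})

test_that("fields outside the grid raise an error naming the field", {
  g <- landscape_grid(5, 5, resolution = 30)
  reg <- rect_field_registry(g, 1, 1, 3, 3)
  reg$polygons[["1"]] <- rect_polygon(-60, 0, 30, 90)
  expect_error(rasterize_fields(reg, g), "1")
})

test_that("reclassify changes exactly the selected cells", {
  lulc <- toy_lulc(matrix(1, 10, 10))
  same <- reclassify(lulc, matrix(FALSE, 10, 10), 4)
  expect_identical(same$codes, lulc$codes)          # empty change set

  sel <- matrix(FALSE, 10, 10); sel[3, 3] <- TRUE
  one <- reclassify(lulc, sel, 4)
  expect_equal(sum(natural_mask(one)) - sum(natural_mask(lulc)), 1)
  expect_identical(one$codes[!sel], lulc$codes[!sel])  # untouched elsewhere
  expect_identical(one$class_table, lulc$class_table)

  sel10 <- matrix(FALSE, 10, 10); sel10[1, 1:10] <- TRUE
  ten <- reclassify(lulc, sel10, 4)
  ag_before <- sum(agricultural_mask(lulc)) * 0.09
  ag_after <- sum(agricultural_mask(ten)) * 0.09
  expect_equal(ag_before - ag_after, 0.9)           # 10 cells x 0.09 ha

  expect_error(reclassify(lulc, sel, 999), "unknown class_id")
})

test_that("natural_mask flags exactly the natural classes", {
  expect_true(all(natural_mask(toy_lulc(matrix(4, 5, 5))) == 1))  # forest
  expect_true(all(natural_mask(toy_lulc(matrix(1, 5, 5))) == 0))  # row crop
  codes <- matrix(1, 20, 20)
  codes[sample(400, 40)] <- 4
  expect_equal(sum(natural_mask(toy_lulc(codes))), 40)
})

test_that("natural mask grows monotonically under reforestation", {
  b <- small_bundle()
  sel <- b$labels == b$registry$fields$field_id[1]
  before <- natural_mask(b$lulc)
  after <- natural_mask(reclassify(b$lulc, sel, 4))
  expect_true(all(after >= before))
})

test_that("LULC, registry and NDVI stacks round-trip through files", {
  b <- small_bundle()
  tmp <- withr::local_tempdir()
  write_lulc(b$lulc, file.path(tmp, "lulc.asc"), file.path(tmp, "classes.csv"))
  back <- read_lulc(file.path(tmp, "lulc.asc"), file.path(tmp, "classes.csv"),
                    buffer_m = b$lulc$buffer_m)
  expect_identical(back$codes, b$lulc$codes)
  expect_equal(back$class_table$is_natural, b$lulc$class_table$is_natural)
  expect_equal(back$grid$origin_y, b$lulc$grid$origin_y)

  reg <- set_marginal_flags(b$registry, abandoned = b$truth$abandoned)
  write_registry(reg, file.path(tmp, "fields.geojson"), file.path(tmp, "history.csv"))
  reg2 <- read_registry(file.path(tmp, "fields.geojson"), file.path(tmp, "history.csv"))
  expect_equal(reg2$fields$area_ha, reg$fields$area_ha, tolerance = 1e-9)
  expect_equal(reg2$fields$abandoned, reg$fields$abandoned)
  expect_equal(reg2$polygons[["3"]][, 1], reg$polygons[["3"]][, 1], tolerance = 1e-9)
  expect_equal(reg2$history$crop_code, reg$history$crop_code)

  sub <- b$ndvi$values[, , 1:3, drop = FALSE]
  write_ndvi_stack(sub, b$lulc$grid, b$ndvi$years[1:3], file.path(tmp, "ndvi"))
  nd <- read_ndvi_stack(file.path(tmp, "ndvi"))
  expect_equal(nd$years, b$ndvi$years[1:3])
  expect_equal(nd$values, sub, tolerance = 1e-5)   # 6 significant digits on disk
})
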