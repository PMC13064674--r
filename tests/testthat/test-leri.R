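test_that("patch counting respects connectivity", {
  # checkerboard: 4-connectivity isolates every cell, 8 joins them all
  cb <- matrix(c(1L, 2L), 4, 4)
  cb[, c(2, 4)] <- rev(c(1L, 2L))
  r <- land_raster(cb, cell_size = 30)
  g <- tessellate(r, unit_size = 120, coverage_min = 0)
  p4 <- patches(r, g, g$unit_id[1], class_code = 1L, connectivity = 4)
  p8 <- patches(r, g, g$unit_id[1], class_code = 1L, connectivity = 8)
  expect_equal(p4$n, sum(cb == 1L))
  expect_equal(p8$n, 1L)
  # one solid block -> a single patch; absent class -> zero
  solid <- land_raster(matrix(2L, 5, 5), cell_size = 30)
  gs <- tessellate(solid, unit_size = 150, coverage_min = 0)
  expect_equal(patches(solid, gs, gs$unit_id[1], 2L)$n, 1L)
  expect_equal(patches(solid, gs, gs$unit_id[1], 3L),
               list(n = 0L, area_km2 = 0))
})

test_that("landscape indices reproduce hand-evaluated formulas", {
  # 1 km^2 unit, one class occupying 0.25 km^2 in 4 separate patches:
  # S = (1 / (2 * 0.25)) * sqrt(4 / 1) = 4; F = 4 / 0.25 = 16 km^-2
  m <- matrix(2L, 20, 20)                       # 50 m cells -> 1 km^2
  m[1:5, 1:5] <- 1L; m[1:5, 16:20] <- 1L
  m[16:20, 1:5] <- 1L; m[16:20, 16:20] <- 1L    # 4 corner patches, 0.25 km^2
  r <- land_raster(m, cell_size = 50)
  g <- tessellate(r, unit_size = 1000, coverage_min = 0)
  met <- landscape_indices(r, g)
  row1 <- met$per_class[met$per_class$class == "cultivated", ]
  expect_equal(row1$n, 4L)
  expect_equal(row1$S, 4)
  expect_equal(row1$F, 16)
  # L, P, T with defaults m=0.6, n=0.4: forest has 1 patch, 0.75 km^2
  rowf <- met$per_class[met$per_class$class == "forest", ]
  expect_equal(row1$L, 4 / 5); expect_equal(rowf$P, 0.75)
  expect_equal(rowf$T, 0.6 * (1 / 5) + 0.4 * 0.75)
  # LERI_k = sum (A_i/A) V_i D_i exactly
  v <- vulnerability_ranks()$normalized
  leri_hand <- 0.25 * v[["cultivated"]] * row1$D +
    0.75 * v[["forest"]] * rowf$D
  expect_equal(met$per_unit$leri, leri_hand)
})

test_that("a single-class unit degenerates to that class's loss index", {
  r <- land_raster(matrix(2L, 10, 10), cell_size = 100)
  g <- tessellate(r, unit_size = 1000, coverage_min = 0)
  met <- landscape_indices(r, g)
  pc <- met$per_class
  expect_equal(pc$L, 1); expect_equal(pc$P, 1); expect_equal(pc$T, 1)
  expect_equal(met$per_unit$leri, pc$R)
})

test_that("fragmentation raises F, S, D and the unit risk index", {
  # same composition, one landscape more fragmented
  a <- matrix(2L, 10, 10); a[, 1:5] <- 1L            # one solid half, 50 cells
  b <- matrix(2L, 10, 10); b[, seq(1, 9, 2)] <- 1L   # 5 stripes, 50 cells
  ra <- land_raster(a, cell_size = 100)
  rb <- land_raster(b, cell_size = 100)
  g <- tessellate(ra, unit_size = 1000, coverage_min = 0)
  ma <- landscape_indices(ra, g, connectivity = 4)
  mb <- landscape_indices(rb, g, connectivity = 4)
  ia <- ma$per_class[ma$per_class$class == "cultivated", ]
  ib <- mb$per_class[mb$per_class$class == "cultivated", ]
  expect_equal(ia$area_km2, ib$area_km2)
  expect_gt(ib$n, ia$n)
  expect_gt(ib$F, ia$F); expect_gt(ib$S, ia$S); expect_gt(ib$D, ia$D)
  expect_gt(mb$per_unit$leri, ma$per_unit$leri)
})

test_that("risk index is invariant to class relabeling", {
  b <- fixture_basin()
  lu <- b$landuse[[1]]
  g <- tessellate(lu, unit_size = 300, coverage_min = 0.5)
  base <- landscape_indices(lu, g)
  # swap codes 1 <-> 2 with a consistent legend and ranks
  sw <- lu$cells
  sw[lu$cells == 1L] <- 2L; sw[lu$cells == 2L] <- 1L
  legend2 <- default_legend()
  legend2[c("1", "2")] <- c("forest", "cultivated")
  lu2 <- land_raster(sw, cell_size = lu$cell_size, origin = lu$origin,
                     legend = legend2)
  rel <- landscape_indices(lu2, g)
  expect_equal(rel$per_unit$leri, base$per_unit$leri)
})

test_that("weights and ranks are validated", {
  expect_error(risk_weights(a = 0.5, b = 0.5, c = 0.2), "sum to 1")
  expect_error(risk_weights(m = 0.5, n = 0.4), "sum to 1")
  expect_error(vulnerability_ranks(c(cultivated = 0)), "positive")
  expect_equal(sum(vulnerability_ranks()$normalized), 1)
})

test_that("leri surface schema matches the esv per-unit schema", {
  b <- fixture_basin()
  lu <- b$landuse[[1]]
  g <- tessellate(lu, unit_size = 300, coverage_min = 0.5)
  met <- landscape_indices(lu, g)
  surf <- leri_surface(met)
  expect_named(surf, c("unit_id", "leri"))
  expect_equal(surf$unit_id, g$unit_id)
})
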