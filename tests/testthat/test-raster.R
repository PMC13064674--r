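test_that("ASCII grid round-trip preserves cells and georeferencing", {
  set.seed(42)
  m <- matrix(sample(c(1:6, NA), 60, replace = TRUE), 6, 10)
  r <- land_raster(m, cell_size = 30, origin = c(500000, 3100000))
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- load_raster(p, kind = "categorical")
  expect_identical(r2$cells, r$cells)
  expect_equal(r2$cell_size, r$cell_size)
  expect_equal(r2$origin, r$origin)

  rc <- cont_raster(matrix(rnorm(60), 6, 10), cell_size = 25)
  write_ascii_grid(rc, p)
  expect_equal(load_raster(p, kind = "continuous")$cells, rc$cells)
})

test_that("unknown class codes and missing georeferencing are rejected", {
  expect_error(land_raster(matrix(c(1, 7), 1), cell_size = 30), "7")
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("1 2 3", "4 5 6"), p)
  expect_error(load_raster(p), "georeferencing")
  # single-class raster loads with the right legend entry
  r <- land_raster(matrix(2L, 3, 3))
  expect_equal(sum(!is.na(r$cells)), 9)
  expect_equal(unname(r$legend["2"]), "forest")
})

test_that("tessellation partitions cells into units by integer division", {
  m <- matrix(1L, 100, 100)
  r <- land_raster(m, cell_size = 30)
  g <- tessellate(r, unit_size = 900, coverage_min = 0.5)
  # 100 cells of 30 m = 3000 m -> 3 full 900 m bands + a partial 300 m band;
  # partial units hold 10x30 or 10x10 cells, all below 50% of 30x30
  expect_equal(nrow(g), 9)
  expect_true(all(g$n_valid == 900))
  g0 <- tessellate(r, unit_size = 900, coverage_min = 0)
  expect_equal(nrow(g0), 16)
  expect_equal(sum(g0$n_valid), sum(!is.na(r$cells)))  # completeness
  # unit_size = cell_size -> one unit per cell
  g1 <- tessellate(land_raster(matrix(1L, 4, 4), cell_size = 30),
                   unit_size = 30, coverage_min = 0)
  expect_equal(nrow(g1), 16)
  expect_true(all(g1$n_valid == 1))
  # all-nodata raster -> zero units
  allna <- land_raster(matrix(NA_integer_, 4, 4), cell_size = 30)
  expect_equal(nrow(tessellate(allna, 60, coverage_min = 0)), 0)
  expect_error(tessellate(r, unit_size = 10), "cell_size")
})

test_that("class areas sum to unit valid area", {
  m <- matrix(2L, 4, 4)
  m[1:2, 1:2] <- 1L
  r <- land_raster(m, cell_size = 30)
  g <- tessellate(r, unit_size = 60, coverage_min = 0)
  ca <- class_area(r, g)
  expect_equal(ca$cultivated[ca$unit_id == g$unit_id[1]], 4 * 900 / 1e6)
  expect_equal(rowSums(ca[, -1]), g$n_valid * 900 / 1e6,
               ignore_attr = TRUE)
  # mixed 2 + 2 cells -> two equal areas
  mm <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  rr <- land_raster(mm, cell_size = 30)
  gg <- tessellate(rr, unit_size = 60, coverage_min = 0)
  cc <- class_area(rr, gg)
  expect_equal(cc$cultivated, cc$forest)
})

test_that("transition matrix conserves area with epoch marginals", {
  b <- fixture_basin()
  a <- b$landuse[[1]]; z <- b$landuse[[2]]
  tm <- transition_matrix(a, z)
  cell_km2 <- (a$cell_size / 1000)^2
  area_a <- table(factor(a$cells, levels = 1:6)) * cell_km2
  area_b <- table(factor(z$cells, levels = 1:6)) * cell_km2
  expect_equal(rowSums(tm), as.numeric(area_a), ignore_attr = TRUE)
  expect_equal(colSums(tm), as.numeric(area_b), ignore_attr = TRUE)
  expect_equal(sum(tm), sum(!is.na(a$cells)) * cell_km2)
  # identical epochs -> diagonal
  td <- transition_matrix(a, a)
  expect_true(all(td[upper.tri(td)] == 0) && all(td[lower.tri(td)] == 0))
  # a single flipped cell -> one off-diagonal entry of one cell-area
  m1 <- matrix(1L, 3, 3); m2 <- m1; m2[2, 2] <- 5L
  t1 <- transition_matrix(land_raster(m1), land_raster(m2))
  expect_equal(t1["cultivated", "construction"], 900 / 1e6)
  expect_equal(sum(t1 > 0), 2)
  expect_error(transition_matrix(land_raster(m1), land_raster(matrix(1L, 2, 2))),
               "mismatch")
})
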