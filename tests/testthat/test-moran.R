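make_full_grid <- function(nr, nc, cell = 10) {
  r <- land_raster(matrix(1L, nr * 2, nc * 2), cell_size = cell)
  tessellate(r, unit_size = 2 * cell, coverage_min = 0)
}

test_that("contiguity schemes give the expected neighbor counts", {
  g <- make_full_grid(3, 3)
  wr <- build_weights(g, scheme = "rook")
  wq <- build_weights(g, scheme = "queen")
  centre <- which(g$urow == 1 & g$ucol == 1)
  expect_equal(length(wr$neighbors[[centre]]), 4)
  expect_equal(length(wq$neighbors[[centre]]), 8)
  corner <- which(g$urow == 0 & g$ucol == 0)
  expect_equal(length(wr$neighbors[[corner]]), 2)
  expect_equal(length(wq$neighbors[[corner]]), 3)
  # symmetry before row-standardization
  wu <- build_weights(g, scheme = "queen", row_standardize = FALSE)
  for (i in seq_len(wu$n)) for (j in wu$neighbors[[i]])
    expect_true(i %in% wu$neighbors[[j]])
})

test_that("isolated units are flagged", {
  m <- matrix(NA_integer_, 6, 6)
  m[1:2, 1:2] <- 1L; m[5:6, 5:6] <- 2L
  r <- land_raster(m, cell_size = 10)
  g <- tessellate(r, unit_size = 20, coverage_min = 0.5)
  expect_warning(w <- build_weights(g), "isolated")
  expect_true(any(lengths(w$neighbors) == 0))
})

test_that("bivariate I matches the double-summation oracle", {
  set.seed(4)
  for (dims in list(c(4, 4), c(5, 6), c(6, 6))) {
    g <- make_full_grid(dims[1], dims[2])
    w <- build_weights(g, scheme = "queen")
    x <- rnorm(nrow(g)); y <- 0.5 * x + rnorm(nrow(g))
    r <- bivariate_moran(x, y, w, permutations = 0)
    expect_equal(r$I, oracle_bimoran(x, y, w), tolerance = 1e-10)
    # y = x reduces to the univariate Moran's I of x
    rx <- bivariate_moran(x, x, w, permutations = 0)
    expect_equal(rx$I, oracle_bimoran(x, x, w), tolerance = 1e-10)
    ryx <- bivariate_moran(y, x, w, permutations = 0)
    expect_equal(ryx$I, oracle_bimoran(y, x, w), tolerance = 1e-10)
    # with symmetric (binary) weights the cross-product is symmetric in its
    # arguments: I(x, y) = I(y, x)
    wb <- build_weights(g, scheme = "queen", row_standardize = FALSE)
    expect_equal(bivariate_moran(x, y, wb, permutations = 0)$I,
                 bivariate_moran(y, x, wb, permutations = 0)$I,
                 tolerance = 1e-12)
  }
})

test_that("literal printed normalization differs from the conventional one
           by exactly n / (n - 1) under row-standardized weights", {
  g <- make_full_grid(5, 5)
  w <- build_weights(g)
  set.seed(7)
  x <- rnorm(25); y <- rnorm(25)
  r <- bivariate_moran(x, y, w, permutations = 0)
  lit <- bivariate_moran_literal(x, y, w)
  expect_equal(lit, r$I * 25 / 24, tolerance = 1e-12)
})

test_that("a spatially coherent pair yields positive I", {
  g <- make_full_grid(6, 6)
  w <- build_weights(g)
  # smooth gradient and its own lag: strong positive cross-correlation
  x <- g$urow + g$ucol
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- vapply(seq_len(w$n), function(i) mean(zx[w$neighbors[[i]]]), 0)
  r <- bivariate_moran(x, y, w, permutations = 0)
  expect_gt(r$I, 0.5)
})

test_that("permutation inference is seeded, reproducible and optional", {
  b <- fixture_basin()
  g <- tessellate(b$landuse[[1]], unit_size = 300, coverage_min = 0.5)
  ev <- esv(b$landuse[[1]], g, unit_value = 1855.65)
  lr <- landscape_indices(b$landuse[[1]], g)
  w <- build_weights(g)
  r0 <- bivariate_moran(ev$per_unit$density, lr$per_unit$leri, w,
                        permutations = 0)
  expect_true(all(r0$clusters == "NS"))
  expect_true(all(is.na(r0$pseudo_p)))
  r1 <- bivariate_moran(ev$per_unit$density, lr$per_unit$leri, w,
                        permutations = 99, seed = 42)
  r2 <- bivariate_moran(ev$per_unit$density, lr$per_unit$leri, w,
                        permutations = 99, seed = 42)
  expect_identical(r1$pseudo_p, r2$pseudo_p)
  expect_identical(r1$clusters, r2$clusters)
  # clusters only where significant
  expect_true(all(r1$pseudo_p[r1$clusters != "NS"] < r1$alpha))
  expect_error(bivariate_moran(rep(1, w$n), rnorm(w$n), w), "variance")
})

test_that("cluster transitions conserve area over the five LISA types", {
  g <- make_full_grid(4, 4)
  lv <- c("NS", "H-H", "L-L", "L-H", "H-L")
  set.seed(2)
  a <- factor(sample(lv, 16, replace = TRUE), levels = lv)
  b <- factor(sample(lv, 16, replace = TRUE), levels = lv)
  tm <- cluster_transitions(a, b, g)
  expect_equal(sum(tm), sum(g$area_km2))
  expect_identical(rownames(tm), lv)
  # identical maps -> diagonal; a single switched unit -> one off-diagonal
  td <- cluster_transitions(a, a, g)
  expect_equal(sum(diag(td)), sum(td))
  b2 <- a; b2[3] <- factor("H-L", levels = lv)
  t2 <- cluster_transitions(a, b2, g)
  off <- sum(t2) - sum(diag(t2))
  expect_equal(off, if (a[3] == "H-L") 0 else g$area_km2[3])
})
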