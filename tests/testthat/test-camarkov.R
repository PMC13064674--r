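test_that("fitted transition matrices are row-stochastic", {
  b <- fixture_basin()
  mod <- fit_markov(b$landuse[[1]], b$landuse[[2]])
  expect_equal(rowSums(mod$T), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(mod$T >= 0))
  # identical epochs -> identity matrix
  modI <- fit_markov(b$landuse[[1]], b$landuse[[1]])
  expect_equal(unname(modI$T), diag(6))
  # a class splitting half-and-half -> 0.5 entries
  a <- land_raster(matrix(1L, 2, 2))
  z <- land_raster(matrix(c(1L, 1L, 5L, 5L), 2, 2))
  m2 <- fit_markov(a, z)
  expect_equal(m2$T["cultivated", "cultivated"], 0.5)
  expect_equal(m2$T["cultivated", "construction"], 0.5)
  # absent classes keep identity rows
  expect_equal(m2$T["water", "water"], 1)
})

test_that("markov projection matches the hand matrix power and conserves area", {
  mod <- structure(list(labels = c("a", "b"),
                        T = matrix(c(0.5, 0, 0.5, 1), 2, 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))),
                        step_years = 10),
                   class = "transition_model")
  p2 <- markov_project(c(a = 100, b = 0), mod, steps = 2)
  expect_equal(unname(p2), c(25, 75))
  expect_equal(sum(p2), 100)
  pI <- markov_project(c(a = 40, b = 60),
                       structure(list(labels = c("a", "b"), T = diag(2),
                                      step_years = 10),
                                 class = "transition_model"), steps = 5)
  expect_equal(unname(pI), c(40, 60))
  expect_error(markov_project(c(a = -1, b = 2), mod), "negative")
  set.seed(6)
  s <- runif(2, 0, 100)
  expect_equal(sum(markov_project(setNames(s, c("a", "b")), mod, 3)), sum(s),
               tolerance = 1e-6)
})

test_that("suitability surfaces follow the rules and constraints", {
  d <- list(x = cont_raster(matrix(1:20, 4, 5), cell_size = 10),
            y = cont_raster(matrix(20:1, 4, 5), cell_size = 10))
  # single increasing driver -> its min-max normalization
  s1 <- build_suitability(d, list(c1 = data.frame(
    driver = "x", direction = "increase", weight = 1)))
  expect_equal(s1$surfaces$c1, (d$x$cells - 1) / 19)
  # two equal-weight drivers -> their mean
  s2 <- build_suitability(d, list(c1 = data.frame(
    driver = c("x", "y"), direction = c("increase", "increase"),
    weight = c(1, 1))))
  expect_equal(s2$surfaces$c1,
               ((d$x$cells - 1) / 19 + (d$y$cells - 1) / 19) / 2)
  # decrease flips; constraint zeroes
  mask <- matrix(1, 4, 5); mask[1, ] <- 0
  s3 <- build_suitability(d, list(c1 = data.frame(
    driver = "x", direction = "decrease", weight = 1)), constraint = mask)
  expect_equal(s3$surfaces$c1[1, ], rep(0, 5))
  expect_equal(s3$surfaces$c1[2:4, ], (1 - (d$x$cells - 1) / 19)[2:4, ])
  # capped preference saturates
  s4 <- build_suitability(d, list(c1 = data.frame(
    driver = "x", direction = "increase", weight = 1, cap = 0.5)))
  expect_equal(max(s4$surfaces$c1), 1)
  expect_equal(s4$surfaces$c1, pmin((d$x$cells - 1) / 19, 0.5) / 0.5)
  expect_error(build_suitability(d, list(c1 = data.frame(
    driver = "z", direction = "increase", weight = 1))), "z")
})

test_that("allocation meets Markov demands within one cell and is seeded", {
  b <- fixture_basin()
  mod <- fit_markov(b$landuse[[1]], b$landuse[[2]])
  suit <- default_suitability(b$drivers, b$landuse[[2]])
  p1 <- ca_allocate(b$landuse[[2]], mod, suit, cfg = ca_config(seed = 9))
  p2 <- ca_allocate(b$landuse[[2]], mod, suit, cfg = ca_config(seed = 9))
  expect_identical(p1$cells, p2$cells)
  counts2 <- table(factor(b$landuse[[2]]$cells, levels = 1:6))
  demand <- markov_project(setNames(as.numeric(counts2), mod$labels), mod)
  final <- table(factor(p1$cells, levels = 1:6))
  expect_true(all(abs(as.numeric(final) - demand) <= 1))
  # identity model leaves the map untouched
  modI <- fit_markov(b$landuse[[2]], b$landuse[[2]])
  pI <- ca_allocate(b$landuse[[2]], modI, suit)
  expect_identical(pI$cells, b$landuse[[2]]$cells)
  # frozen water never converts
  expect_true(all(p1$cells[b$landuse[[2]]$cells == 4L] == 4L))
})

test_that("allocation converts the unambiguously best-scoring cells", {
  # 1 -> 5 demand of 4 cells; suitability has a unique top-4 plateau
  m <- matrix(1L, 6, 6)
  mod <- structure(list(labels = unname(default_legend()),
                        T = diag(6), step_years = 10),
                   class = "transition_model")
  dimnames(mod$T) <- list(mod$labels, mod$labels)
  mod$T["cultivated", "cultivated"] <- 32 / 36
  mod$T["cultivated", "construction"] <- 4 / 36
  sgrid <- matrix(0.1, 6, 6); sgrid[2:3, 2:3] <- 0.9
  suit <- structure(list(surfaces = stats::setNames(
    rep(list(matrix(0, 6, 6)), 6), mod$labels), constraint = NULL),
    class = "suitability_stack")
  suit$surfaces$construction <- sgrid
  r <- land_raster(m, cell_size = 30)
  out <- ca_allocate(r, mod, suit, cfg = ca_config(iterations = 1))
  expect_equal(which(out$cells == 5L),
               which(sgrid == 0.9))
})

test_that("kappa matches closed forms and detects chance agreement", {
  b <- fixture_basin()
  expect_equal(kappa_agreement(b$landuse[[1]], b$landuse[[1]]), 1)
  # 10% flips between two equal classes: po = 0.9, pe = 0.5 -> kappa = 0.8
  set.seed(17)
  m <- matrix(rep(c(1L, 2L), each = 5000), 100, 100)
  r1 <- land_raster(m, cell_size = 30)
  m2 <- m
  flip <- sample(length(m), 1000)
  m2[flip] <- 3L - m2[flip]
  r2 <- land_raster(m2, cell_size = 30)
  k <- kappa_agreement(r1, r2)
  expect_equal(k, 0.8, tolerance = 0.02)
  # independent maps -> kappa near zero
  ks <- vapply(1:10, function(sd) {
    set.seed(sd)
    a <- land_raster(matrix(sample(1:4, 1e5, TRUE), 250, 400), cell_size = 30)
    z <- land_raster(matrix(sample(1:4, 1e5, TRUE), 250, 400), cell_size = 30)
    kappa_agreement(a, z)
  }, 0)
  expect_true(all(abs(ks) < 0.02))
  # both maps constant and identical -> kappa 1 by convention
  c1 <- land_raster(matrix(2L, 3, 3))
  expect_equal(kappa_agreement(c1, c1), 1)
})

test_that("the fitted CA beats persistence on held-out epochs (10 seeds)", {
  wins <- vapply(1:10, function(sd) {
    b <- fixture_basin(seed = sd)
    mod <- fit_markov(b$landuse[[1]], b$landuse[[2]])
    suit <- default_suitability(b$drivers, b$landuse[[2]])
    pred <- ca_allocate(b$landuse[[2]], mod, suit)
    kappa_agreement(b$landuse[[3]], pred) >
      kappa_agreement(b$landuse[[3]], b$landuse[[2]])
  }, TRUE)
  expect_gte(sum(wins), 6)
})
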