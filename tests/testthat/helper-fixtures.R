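# Shared fixtures, generated in code. The basin is cached per (seed, epochs)
# so test files can reuse it without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

fixture_basin <- function(seed = 1L, epochs = 3L) {
  key <- paste0("b", seed, "_", epochs)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_basin(landscape_spec(seed = seed),
                                            epochs = epochs)
  }
  .fixture_cache[[key]]
}

# small hand-built land raster: `codes` is a matrix of class codes
tiny_raster <- function(codes, cell_size = 30) {
  land_raster(as.matrix(codes), cell_size = cell_size)
}

# brute-force bivariate cross-Moran: explicit dense-W double summation of
# z-scored x against z-scored y (row-standardized contiguity)
oracle_bimoran <- function(x, y, w) {
  n <- length(x)
  W <- matrix(0, n, n)
  for (i in seq_len(n))
    W[i, w$neighbors[[i]]] <- w$weights[[i]]
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    acc <- acc + W[i, j] * zx[i] * zy[j]
  acc / n
}

# exhaustive optimal k-partition of sorted values by within-class SSD
oracle_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  # all ordered partitions: choose k-1 cut positions among n-1 gaps
  cuts <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, ci], n)
    tot <- sum(vapply(seq_len(k), function(g)
      ssd(x[(bounds[g] + 1):bounds[g + 1]]), 0))
    best <- min(best, tot)
  }
  best
}

# eigen-decomposition oracle for the weighted SDE: axes = sqrt of the
# eigenvalues of the weighted covariance, azimuth = major eigenvector bearing
oracle_sde <- function(x, y, w) {
  cx <- sum(w * x) / sum(w); cy <- sum(w * y) / sum(w)
  dx <- x - cx; dy <- y - cy
  C <- matrix(c(sum(w * dx^2), sum(w * dx * dy),
                sum(w * dx * dy), sum(w * dy^2)), 2) / sum(w)
  e <- eigen(C, symmetric = TRUE)
  v <- e$vectors[, 1]
  list(centre = c(cx, cy),
       major = sqrt(e$values[1]), minor = sqrt(max(e$values[2], 0)),
       azimuth_deg = (atan2(v[1], v[2]) * 180 / pi) %% 180)
}
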