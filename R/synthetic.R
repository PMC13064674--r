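# Seeded synthetic dry-valley basins: a low flat valley running north-south
# (cropland, construction, river and lakes), forested mid-slopes, grassland
# ecotones and alpine unused land, plus driver surfaces correlated with the
# pattern. Everything is deterministic under the spec's seed.

#' Specification of a synthetic dry-valley landscape
#'
#' Defaults reproduce the study conditions the analysis assumes: a basin whose
#' class composition matches the reported shares (forest ~63%, cultivated
#' ~25%, grassland ~9%, water/construction/unused < 2% each), elevations
#' spanning 993-5076 m, and epoch-to-epoch change dominated by construction
#' expansion in the valley and forest/grassland exchange on the slopes.
#'
#' @param rows,cols Grid dimensions (cells).
#' @param cell_size Cell edge in metres.
#' @param seed Integer seed governing every stochastic component.
#' @param valley_axis Column index of the valley centre line.
#' @param class_fractions Named target fractions for the six classes
#'   (must sum to 1).
#' @param change_rates Named list of per-epoch conversion intensities in
#'   \[0, 1\]: `construction_expansion` (fraction of the construction area
#'   added per epoch from adjacent cultivated land), `grass_to_forest` and
#'   `forest_to_grass` (fractions of ecotone cells exchanged per epoch), and
#'   `cultivated_to_construction` kept for clarity of the expansion source.
#' @param elev_range Elevation range in metres.
#' @param noise Relative amplitude of the smooth terrain noise (0 disables).
#' @param drivers Character vector of driver surfaces to emit; see
#'   [generate_drivers()].
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(rows = 120, cols = 120, cell_size = 30, seed = 1,
                           valley_axis = round(cols / 2),
                           class_fractions = c(cultivated = 0.2525,
                                               forest = 0.6302,
                                               grassland = 0.0911,
                                               water = 0.0100,
                                               construction = 0.0110,
                                               unused = 0.0052),
                           change_rates = list(construction_expansion = 0.35,
                                               grass_to_forest = 0.10,
                                               forest_to_grass = 0.005),
                           elev_range = c(993, 5076),
                           noise = 0.15,
                           drivers = default_driver_set()) {
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (any(unlist(change_rates) < 0 | unlist(change_rates) > 1))
    stop("change_rates must lie in [0, 1]")
  structure(list(rows = rows, cols = cols, cell_size = cell_size, seed = seed,
                 valley_axis = valley_axis, class_fractions = class_fractions,
                 change_rates = change_rates, elev_range = elev_range,
                 noise = noise, drivers = drivers),
            class = "landscape_spec")
}

#' @rdname landscape_spec
#' @export
default_driver_set <- function() {
  c("elevation", "slope", "aspect", "relief",
    "temperature", "evaporation", "humidity", "precipitation",
    "dist_river", "dist_road", "dist_centre",
    "population", "gdp", "agri_potential")
}

# Filtered white noise: white Gaussian field smoothed by repeated separable
# box filters, rescaled to zero mean unit sd. Deterministic under the seed.
smooth_noise <- function(rows, cols, passes = 4L, width = 9L) {
  m <- matrix(stats::rnorm(rows * cols), rows, cols)
  k <- rep(1 / width, width)
  pad <- (width - 1L) %/% 2L
  for (p in seq_len(passes)) {
    # reflect-pad then filter rows and columns
    mp <- m[c(rev(seq_len(pad)), seq_len(rows), rows + 1L - rev(seq_len(pad))), ]
    m <- apply(mp, 2L, function(v) stats::filter(v, k, sides = 2)[pad + seq_len(rows)])
    mp <- m[, c(rev(seq_len(pad)), seq_len(cols), cols + 1L - rev(seq_len(pad)))]
    m <- t(apply(mp, 1L, function(v) stats::filter(v, k, sides = 2)[pad + seq_len(cols)]))
  }
  (m - mean(m)) / stats::sd(m)
}

#' Generate the basin elevation surface
#'
#' A V-shaped valley profile (minimum along the valley axis, rising with
#' distance from it) plus seeded smooth noise, rescaled to the spec's
#' elevation range.
#'
#' @param spec A [landscape_spec()].
#' @return A `cont_raster` of elevation in metres.
#' @export
generate_elevation <- function(spec) {
  set.seed(spec$seed)
  d <- abs(col(matrix(0, spec$rows, spec$cols)) - spec$valley_axis) /
    max(spec$valley_axis, spec$cols - spec$valley_axis)
  base <- d^1.3
  if (spec$noise > 0) {
    n <- smooth_noise(spec$rows, spec$cols)
    base <- base + spec$noise * n * diff(range(base))
  }
  base <- base - min(base)
  elev <- spec$elev_range[1] +
    base / max(base) * diff(spec$elev_range)
  cont_raster(elev, cell_size = spec$cell_size,
              origin = c(0, spec$rows * spec$cell_size))
}

# linear feature cells of the synthetic river (follows the valley axis with a
# gentle seeded meander) and the road (parallel, offset east)
valley_line <- function(spec, offset = 0L, wobble = 2) {
  set.seed(spec$seed + 101L + offset)
  drift <- round(stats::filter(stats::rnorm(spec$rows, 0, wobble),
                               rep(1 / 15, 15), sides = 2, circular = TRUE))
  col_idx <- pmin(pmax(spec$valley_axis + offset + drift, 1L), spec$cols)
  cbind(row = seq_len(spec$rows), col = as.integer(col_idx))
}

#' Generate a land-use raster for one epoch
#'
#' Epoch 1 assigns classes by elevation band (band cut points are elevation
#' quantiles at the cumulative target fractions) with seeded ecotone mixing:
#' the lowest band holds cultivated land, construction (clustered near the
#' valley axis) and water (the river line plus seeded lake patches); forest
#' occupies mid-slopes, grassland the high band and unused land the highest
#' band. Epochs > 1 apply the spec's `change_rates` to the previous epoch
#' (first-order dynamics), so the process is Markovian by construction.
#'
#' @param spec A [landscape_spec()].
#' @param elevation Elevation raster from [generate_elevation()].
#' @param epoch Epoch number (1-based).
#' @return A `land_raster`.
#' @export
generate_landuse <- function(spec, elevation, epoch = 1L) {
  if (!all(dim(elevation$cells) == c(spec$rows, spec$cols)))
    stop("elevation shape does not match spec")
  lu <- generate_landuse_base(spec, elevation)
  if (epoch > 1L)
    for (e in seq_len(epoch - 1L))
      lu <- apply_epoch_change(spec, lu, e)
  lu
}

generate_landuse_base <- function(spec, elevation) {
  set.seed(spec$seed + 7L)
  f <- spec$class_fractions
  elev <- elevation$cells
  # ecotone mixing: jitter elevation before banding so band edges interdigitate
  mix <- smooth_noise(spec$rows, spec$cols, passes = 2L, width = 5L)
  e_mix <- elev + mix * 0.02 * diff(range(elev))
  cum <- cumsum(c(f[["cultivated"]] + f[["construction"]] + f[["water"]],
                  f[["forest"]], f[["grassland"]]))
  cuts <- stats::quantile(e_mix, probs = cum, names = FALSE)
  cls <- matrix(6L, spec$rows, spec$cols)          # unused (highest band)
  cls[e_mix < cuts[3]] <- 3L                        # grassland
  cls[e_mix < cuts[2]] <- 2L                        # forest
  low <- e_mix < cuts[1]
  cls[low] <- 1L                                    # cultivated valley floor
  # water: river line plus seeded lake patches, valley band only
  n_cells <- spec$rows * spec$cols
  river <- valley_line(spec, offset = 0L)
  river_ok <- low[river]
  cls[river[river_ok, , drop = FALSE]] <- 4L
  n_water_target <- round(f[["water"]] * n_cells)
  n_lake <- max(n_water_target - sum(river_ok), 0L)
  low_idx <- which(low & cls == 1L)
  if (n_lake > 0L && length(low_idx)) {
    seeds <- sample(low_idx, max(1L, round(n_lake / 25)))
    lake <- grow_patches(cls, seeds, n_lake, within = low & cls == 1L,
                         rows = spec$rows)
    cls[lake] <- 4L
  }
  # construction: clustered blobs near the valley axis within the low band
  n_con <- round(f[["construction"]] * n_cells)
  cand <- which(low & cls == 1L)
  if (n_con > 0L && length(cand)) {
    dcol <- abs(((cand - 1L) %/% spec$rows) + 1L - spec$valley_axis)
    seeds <- sample(cand, max(1L, round(n_con / 40)),
                    prob = exp(-dcol / 6))
    con <- grow_patches(cls, seeds, n_con, within = low & cls == 1L,
                        rows = spec$rows)
    cls[con] <- 5L
  }
  land_raster(cls, cell_size = spec$cell_size,
              origin = c(0, spec$rows * spec$cell_size))
}

# grow connected patches from seed cells (column-major linear indices) until
# n_target cells are reached, staying inside `within`
grow_patches <- function(cls, seeds, n_target, within, rows) {
  taken <- seeds
  frontier <- seeds
  in_ok <- which(within)
  while (length(taken) < n_target && length(frontier)) {
    nb <- unique(c(frontier - 1L, frontier + 1L,
                   frontier - rows, frontier + rows))
    nb <- nb[nb >= 1L & nb <= length(cls)]
    nb <- setdiff(intersect(nb, in_ok), taken)
    if (!length(nb)) break
    need <- n_target - length(taken)
    if (length(nb) > need) nb <- sample(nb, need)
    taken <- c(taken, nb)
    frontier <- nb
  }
  taken
}

apply_epoch_change <- function(spec, lu, step) {
  set.seed(spec$seed + 1000L * step + 13L)
  cls <- lu$cells
  rows <- nrow(cls)
  rates <- spec$change_rates
  # construction expansion: convert cultivated cells adjacent to construction
  r_con <- rates$construction_expansion %||% 0
  if (r_con > 0) {
    n_new <- round(sum(cls == 5L) * r_con)
    while (n_new > 0L) {
      con <- which(cls == 5L)
      nb <- unique(c(con - 1L, con + 1L, con - rows, con + rows))
      nb <- nb[nb >= 1L & nb <= length(cls)]
      nb <- nb[cls[nb] == 1L]
      if (!length(nb)) break
      # densify: prefer candidates with the most built-up neighbors
      score <- neighbor_count(cls, nb, 5L, rows) + stats::runif(length(nb))
      take_n <- min(n_new, length(nb))
      take <- nb[order(score, decreasing = TRUE)][seq_len(take_n)]
      cls[take] <- 5L
      n_new <- n_new - length(take)
    }
  }
  # forest <-> grassland exchange on the ecotone (cells adjacent to the other
  # class); both directions are sampled from the epoch-start state so the
  # exchanges cannot cancel each other
  pick <- function(cls0, from, to, rate) {
    if (rate <= 0) return(integer(0))
    idx <- which(cls0 == from)
    if (!length(idx)) return(integer(0))
    nb_to <- (cls0[pmax(idx - 1L, 1L)] == to) |
      (cls0[pmin(idx + 1L, length(cls0))] == to) |
      (cls0[pmax(idx - rows, 1L)] == to) |
      (cls0[pmin(idx + rows, length(cls0))] == to)
    eco <- idx[nb_to]
    n_flip <- round(length(idx) * rate)
    if (n_flip == 0L || !length(eco)) return(integer(0))
    # the class advances along its edge: deepest-indented cells flip first
    score <- neighbor_count(cls0, eco, to, rows) + stats::runif(length(eco))
    eco[order(score, decreasing = TRUE)][seq_len(min(n_flip, length(eco)))]
  }
  cls0 <- cls
  g2f <- pick(cls0, 3L, 2L, rates$grass_to_forest %||% 0)
  f2g <- pick(cls0, 2L, 3L, rates$forest_to_grass %||% 0)
  cls[g2f] <- 2L
  cls[f2g] <- 3L
  land_raster(cls, cell_size = lu$cell_size, origin = lu$origin,
              legend = lu$legend)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of 8-neighbors of each `idx` cell (column-major) holding class `code`
neighbor_count <- function(cls, idx, code, rows) {
  n <- length(cls)
  cnt <- integer(length(idx))
  for (off in c(-1L, 1L, -rows, rows, -rows - 1L, -rows + 1L, rows - 1L, rows + 1L)) {
    nb <- idx + off
    ok <- nb >= 1L & nb <= n
    cnt[ok] <- cnt[ok] + (cls[nb[ok]] == code)
  }
  cnt
}

# Euclidean distance (in cells) from every cell to the nearest feature cell
distance_to <- function(rows, cols, feature_rc) {
  if (nrow(feature_rc) == 0L) return(matrix(Inf, rows, cols))
  r <- row(matrix(0, rows, cols)); c <- col(matrix(0, rows, cols))
  d2 <- matrix(Inf, rows, cols)
  for (i in seq_len(nrow(feature_rc)))
    d2 <- pmin(d2, (r - feature_rc[i, 1])^2 + (c - feature_rc[i, 2])^2)
  sqrt(d2)
}

#' Generate driver surfaces correlated with the landscape
#'
#' Emits analogues of the usual natural/socioeconomic driver set: terrain
#' derivatives of the elevation surface (slope, aspect, relief by finite
#' differences), climate surfaces as affine functions of elevation plus
#' seeded smooth noise, Euclidean distance surfaces to the synthetic river,
#' road and administrative centre, population/GDP surfaces decaying with
#' distance from the valley, and `agri_potential` — a surface built to be the
#' dominant correlate of the per-cell ecosystem-service pattern, planted so
#' driver-attribution methods have a known ground truth to recover.
#'
#' @param spec A [landscape_spec()].
#' @param elevation Elevation raster.
#' @param landuse Land-use raster of the same epoch.
#' @return Named list of `cont_raster`s (those in `spec$drivers`).
#' @export
generate_drivers <- function(spec, elevation, landuse) {
  if (!identical(dim(elevation$cells), dim(landuse$cells)))
    stop("driver input shapes differ")
  set.seed(spec$seed + 31L)
  rows <- spec$rows; cols <- spec$cols; s <- spec$cell_size
  elev <- elevation$cells
  out <- list()
  mk <- function(m) cont_raster(m, cell_size = s, origin = elevation$origin)

  # terrain derivatives (central differences, edges replicated)
  gx <- (elev[, pmin(seq_len(cols) + 1L, cols)] -
           elev[, pmax(seq_len(cols) - 1L, 1L)]) / (2 * s)
  gy <- (elev[pmin(seq_len(rows) + 1L, rows), ] -
           elev[pmax(seq_len(rows) - 1L, 1L), ]) / (2 * s)
  out$elevation <- mk(elev)
  out$slope <- mk(atan(sqrt(gx^2 + gy^2)) * 180 / pi)
  out$aspect <- mk((atan2(gy, -gx) * 180 / pi) %% 360)
  rel <- matrix(0, rows, cols)
  for (dr in -1:1) for (dc in -1:1) {
    sh <- elev[pmin(pmax(seq_len(rows) + dr, 1L), rows),
               pmin(pmax(seq_len(cols) + dc, 1L), cols)]
    rel <- pmax(rel, abs(sh - elev))
  }
  out$relief <- mk(rel)

  clim <- function(base, lapse, amp) {
    n <- smooth_noise(rows, cols, passes = 3L, width = 7L)
    base + lapse * (elev - min(elev)) / 1000 + amp * n
  }
  out$temperature <- mk(clim(20, -5.8, 0.8))       # degC, lapse ~5.8/km
  out$evaporation <- mk(clim(1800, -180, 60))      # mm/yr, drier valley floor
  out$humidity <- mk(clim(55, 4.5, 2))             # %, moister uplands
  out$precipitation <- mk(clim(900, 95, 40))       # mm/yr

  river <- valley_line(spec, offset = 0L)
  road <- valley_line(spec, offset = max(3L, round(cols * 0.06)))
  centre <- matrix(c(round(rows / 2), spec$valley_axis), 1L)
  out$dist_river <- mk(distance_to(rows, cols, river) * s)
  out$dist_road <- mk(distance_to(rows, cols, road) * s)
  out$dist_centre <- mk(distance_to(rows, cols, centre) * s)

  dval <- abs(col(elev) - spec$valley_axis) * s
  out$population <- mk(5000 * exp(-dval / (0.15 * cols * s)) +
                         50 * abs(smooth_noise(rows, cols)))
  out$gdp <- mk(2000 * exp(-dval / (0.12 * cols * s)) +
                  20 * abs(smooth_noise(rows, cols)))

  # planted dominant driver: smoothed per-cell total service equivalent of the
  # land-use map plus small noise, so it is the true top correlate of ESV
  eq <- rowSums(as.matrix(default_equivalent_table()[, -1]))
  w <- matrix(eq[landuse$cells], rows, cols)
  wpad <- w
  for (p in 1:2) {
    acc <- wpad * 0
    for (dr in -1:1) for (dc in -1:1)
      acc <- acc + wpad[pmin(pmax(seq_len(rows) + dr, 1L), rows),
                        pmin(pmax(seq_len(cols) + dc, 1L), cols)]
    wpad <- acc / 9
  }
  out$agri_potential <- mk(wpad + 0.05 * stats::sd(wpad) *
                             smooth_noise(rows, cols, passes = 2L))

  out[intersect(spec$drivers, names(out))]
}

#' Generate a complete multi-epoch synthetic basin
#'
#' @param spec A [landscape_spec()].
#' @param epochs Number of land-use epochs to emit.
#' @return List with `elevation`, `landuse` (list of `land_raster`s) and
#'   `drivers` (drivers of the first epoch).
#' @export
generate_basin <- function(spec, epochs = 3L) {
  elev <- generate_elevation(spec)
  lus <- vector("list", epochs)
  lus[[1]] <- generate_landuse(spec, elev, epoch = 1L)
  if (epochs > 1L)
    for (e in 2:epochs)
      lus[[e]] <- apply_epoch_change(spec, lus[[e - 1L]], e - 1L)
  list(elevation = elev, landuse = lus,
       drivers = generate_drivers(spec, elev, lus[[1]]))
}
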