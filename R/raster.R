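#' @details
#' Rasters are stored as plain numeric/integer matrices with georeferencing
#' attributes: row 1 is the northmost row, and cell (r, c) covers the half-open
#' square \[origin_x + (c-1)s, origin_x + c\*s) x (origin_y - r\*s, origin_y -
#' (r-1)s\], s being the cell edge in metres of a projected CRS.
#' @keywords internal
"_PACKAGE"

#' Default land-use legend
#'
#' Class codes 1..6 for the six aggregate land-use classes used throughout:
#' 1 cultivated, 2 forest, 3 grassland, 4 water, 5 construction, 6 unused.
#' Source rasters with other codings (e.g. GlobeLand30) should be remapped to
#' these codes via the `legend`/`remap` arguments of [load_raster()].
#'
#' @return Named character vector mapping code (name) to class name.
#' @export
default_legend <- function() {
  c("1" = "cultivated", "2" = "forest", "3" = "grassland",
    "4" = "water", "5" = "construction", "6" = "unused")
}

#' Construct a categorical land-use raster
#'
#' @param cells Integer matrix of class codes; `NA` marks nodata. Row 1 is the
#'   northmost row.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2, projected (x, y) of the grid's top-left
#'   (northwest) corner.
#' @param legend Named character vector mapping class codes to class names.
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(cells, cell_size = 30,
                        origin = c(0, nrow(cells) * cell_size),
                        legend = default_legend()) {
  cells <- as.matrix(cells)
  if (length(cells) == 0L) stop("raster grid must be non-empty")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  storage.mode(cells) <- "integer"
  codes <- sort(unique(cells[!is.na(cells)]))
  unknown <- setdiff(codes, as.integer(names(legend)))
  if (length(unknown))
    stop("unknown class code(s) not in legend: ", paste(unknown, collapse = ", "))
  structure(list(cells = cells, cell_size = cell_size,
                 origin = as.numeric(origin), legend = legend),
            class = "land_raster")
}

#' Construct a continuous raster
#'
#' @inheritParams land_raster
#' @param values Numeric matrix; `NA` marks nodata.
#' @return An object of class `cont_raster`.
#' @export
cont_raster <- function(values, cell_size = 30,
                        origin = c(0, nrow(values) * cell_size)) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("raster grid must be non-empty")
  if (cell_size <= 0) stop("cell_size must be positive")
  structure(list(cells = values, cell_size = cell_size,
                 origin = as.numeric(origin)),
            class = "cont_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat("land_raster:", nrow(x$cells), "x", ncol(x$cells), "cells,",
      x$cell_size, "m; classes:",
      paste(x$legend[names(x$legend) %in% unique(x$cells)], collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cont_raster <- function(x, ...) {
  rng <- range(x$cells, na.rm = TRUE)
  cat("cont_raster:", nrow(x$cells), "x", ncol(x$cells), "cells,",
      x$cell_size, "m; range", signif(rng[1], 5), "-", signif(rng[2], 5), "\n")
  invisible(x)
}

#' Load a raster from an ESRI ASCII grid file
#'
#' Parses the standard six-line ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`) followed by row-major values, north row first.
#'
#' @param path Path to a `.asc` file.
#' @param kind `"categorical"` (returns a [land_raster()]) or `"continuous"`.
#' @param legend Legend for categorical rasters; codes absent from it raise an
#'   error naming the offending code.
#' @return A `land_raster` or `cont_raster`.
#' @export
load_raster <- function(path, kind = c("categorical", "continuous"),
                        legend = default_legend()) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)) ||
      !any(c("xllcorner", "xllcenter") %in% names(hdr)) ||
      !any(c("yllcorner", "yllcenter") %in% names(hdr)))
    stop("missing georeferencing header in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  s <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - s / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - s / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values, got ", length(vals))
  vals[vals == nodata] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  origin <- c(xll, yll + nr * s)
  if (kind == "categorical") {
    if (any(!is.na(m) & m != round(m)))
      stop("non-integer values in categorical raster ", path)
    land_raster(m, cell_size = s, origin = origin, legend = legend)
  } else {
    cont_raster(m, cell_size = s, origin = origin)
  }
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param raster A `land_raster` or `cont_raster`.
#' @param path Output path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  m <- raster$cells
  nr <- nrow(m); nc <- ncol(m); s <- raster$cell_size
  hdr <- c(paste("ncols", nc), paste("nrows", nr),
           paste("xllcorner", format(raster$origin[1], scientific = FALSE)),
           paste("yllcorner", format(raster$origin[2] - nr * s, scientific = FALSE)),
           paste("cellsize", format(s, scientific = FALSE)),
           paste("NODATA_value", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Projected coordinates of every cell centre
#' @param raster A raster object.
#' @return List with matrices `x` and `y` of cell-centre coordinates.
#' @keywords internal
cell_centres <- function(raster) {
  s <- raster$cell_size
  nr <- nrow(raster$cells); nc <- ncol(raster$cells)
  x <- matrix(raster$origin[1] + (seq_len(nc) - 0.5) * s, nr, nc, byrow = TRUE)
  y <- matrix(raster$origin[2] - (seq_len(nr) - 0.5) * s, nr, nc)
  list(x = x, y = y)
}

#' Tessellate a raster into square evaluation units
#'
#' Bins cell centres into an axis-aligned grid of `unit_size` x `unit_size`
#' squares anchored at the raster origin (e.g. the conventional 1 km x 1 km
#' evaluation grid). Units whose valid-cell fraction (relative to a full
#' unit's nominal cell count) falls below `coverage_min` are dropped.
#'
#' @param raster A `land_raster`.
#' @param unit_size Unit edge length in metres; must be >= `cell_size`.
#' @param coverage_min Minimum valid-cell fraction for a unit to be retained.
#' @return A data.frame of class `eval_grid` with one row per retained unit:
#'   `unit_id`, `urow`, `ucol` (unit grid position), `n_valid` (valid cells),
#'   `centroid_x`, `centroid_y` (centre of the unit's nominal extent), and
#'   `area_km2` (valid area). Attributes carry the tessellation geometry.
#' @export
tessellate <- function(raster, unit_size = 1000, coverage_min = 0.5) {
  s <- raster$cell_size
  if (unit_size < s) stop("unit_size must be at least cell_size")
  nr <- nrow(raster$cells); nc <- ncol(raster$cells)
  r <- row(raster$cells); c <- col(raster$cells)
  # bin by cell-centre offset from the origin
  urow <- floor(((r - 0.5) * s) / unit_size)
  ucol <- floor(((c - 0.5) * s) / unit_size)
  nucol <- max(ucol) + 1L
  uid <- urow * nucol + ucol + 1L
  valid <- !is.na(raster$cells)
  n_valid <- tabulate(uid[valid], nbins = max(uid))
  full <- (unit_size / s)^2
  keep <- which(n_valid / full >= coverage_min & n_valid > 0L)
  if (coverage_min <= 0) keep <- which(n_valid > 0L)
  ur <- (keep - 1L) %/% nucol
  uc <- (keep - 1L) %% nucol
  grid <- data.frame(
    unit_id = keep,
    urow = ur, ucol = uc,
    n_valid = n_valid[keep],
    centroid_x = raster$origin[1] + (uc + 0.5) * unit_size,
    centroid_y = raster$origin[2] - (ur + 0.5) * unit_size,
    area_km2 = n_valid[keep] * (s / 1000)^2
  )
  attr(grid, "unit_size") <- unit_size
  attr(grid, "cell_size") <- s
  attr(grid, "nucol") <- nucol
  attr(grid, "nurow") <- max(urow) + 1L
  attr(grid, "coverage_min") <- coverage_min
  class(grid) <- c("eval_grid", "data.frame")
  grid
}

#' Per-cell unit membership
#'
#' @param raster Raster the grid was derived from.
#' @param grid An `eval_grid`.
#' @return Integer matrix of `unit_id`; `NA` where the cell is nodata or its
#'   unit was dropped by the coverage threshold.
#' @export
unit_index <- function(raster, grid) {
  s <- raster$cell_size
  unit_size <- attr(grid, "unit_size")
  nucol <- attr(grid, "nucol")
  urow <- floor(((row(raster$cells) - 0.5) * s) / unit_size)
  ucol <- floor(((col(raster$cells) - 0.5) * s) / unit_size)
  uid <- urow * nucol + ucol + 1L
  uid[is.na(raster$cells) | !(uid %in% grid$unit_id)] <- NA_integer_
  uid
}

#' Per-unit land-class areas
#'
#' Area (km^2) of each land-use class within each evaluation unit: the
#' A_ki terms of the risk index and the A_i terms of the valuation sum.
#'
#' @inheritParams unit_index
#' @return Data.frame: `unit_id` plus one column per legend class (km^2).
#' @export
class_area <- function(raster, grid) {
  uid <- unit_index(raster, grid)
  ok <- !is.na(uid)
  codes <- as.integer(names(raster$legend))
  cls <- factor(raster$cells[ok], levels = codes)
  tab <- table(factor(uid[ok], levels = grid$unit_id), cls)
  areas <- as.data.frame.matrix(tab) * (raster$cell_size / 1000)^2
  names(areas) <- unname(raster$legend[as.character(codes)])
  cbind(data.frame(unit_id = grid$unit_id), areas)
}

#' Land-use transition matrix between two epochs
#'
#' @param a,b Aligned `land_raster`s (same shape, cell size and origin).
#' @return An `area_matrix`: square matrix of areas (km^2), entry (i, j) being
#'   the area mapped class i in `a` and class j in `b`; cells valid in both.
#' @export
transition_matrix <- function(a, b) {
  if (!identical(dim(a$cells), dim(b$cells)))
    stop("raster shape mismatch")
  if (a$cell_size != b$cell_size || !isTRUE(all.equal(a$origin, b$origin)))
    stop("raster georeferencing mismatch")
  codes <- as.integer(names(a$legend))
  ok <- !is.na(a$cells) & !is.na(b$cells)
  tab <- table(factor(a$cells[ok], levels = codes),
               factor(b$cells[ok], levels = codes))
  m <- unclass(tab) * (a$cell_size / 1000)^2
  labels <- unname(a$legend[as.character(codes)])
  dimnames(m) <- list(from = labels, to = labels)
  structure(m, class = c("area_matrix", class(m)))
}

#' Cross-tabulated area matrix for arbitrary per-unit labels
#'
#' Shared accounting for grade-to-grade and LISA-cluster transitions: entry
#' (g, h) is the total unit area labelled g in `labels_a` and h in `labels_b`.
#'
#' @param labels_a,labels_b Per-unit labels aligned with `grid` rows.
#' @param grid An `eval_grid` supplying unit areas.
#' @param levels Label universe (ordering of the matrix).
#' @return An `area_matrix` (km^2) plus attribute `prop_delta`, the per-label
#'   area-proportion change (column share minus row share, percent).
#' @export
label_transitions <- function(labels_a, labels_b, grid,
                              levels = sort(unique(c(labels_a, labels_b)))) {
  if (length(labels_a) != nrow(grid) || length(labels_b) != nrow(grid))
    stop("labels must align with the unit set of the grid")
  fa <- factor(labels_a, levels = levels)
  fb <- factor(labels_b, levels = levels)
  m <- matrix(0, length(levels), length(levels),
              dimnames = list(from = levels, to = levels))
  for (i in seq_len(nrow(grid)))
    m[fa[i], fb[i]] <- m[fa[i], fb[i]] + grid$area_km2[i]
  tot <- sum(m)
  attr(m, "prop_delta") <- 100 * (colSums(m) - rowSums(m)) / tot
  structure(m, class = c("area_matrix", class(m)))
}

#' Export evaluation units as GeoJSON polygons
#'
#' @param grid An `eval_grid`.
#' @param path Output path.
#' @param values Optional named list of per-unit property vectors.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path, values = list()) {
  half <- attr(grid, "unit_size") / 2
  feats <- vapply(seq_len(nrow(grid)), function(i) {
    cx <- grid$centroid_x[i]; cy <- grid$centroid_y[i]
    ring <- sprintf("[%.3f,%.3f]",
                    c(cx - half, cx + half, cx + half, cx - half, cx - half),
                    c(cy - half, cy - half, cy + half, cy + half, cy - half))
    props <- c(sprintf('"unit_id":%d', grid$unit_id[i]),
               vapply(names(values), function(nm)
                 sprintf('"%s":%s', nm,
                         if (is.numeric(values[[nm]])) format(values[[nm]][i])
                         else sprintf('"%s"', values[[nm]][i])), ""))
    sprintf('{"type":"Feature","properties":{%s},"geometry":{"type":"Polygon","coordinates":[[%s]]}}',
            paste(props, collapse = ","), paste(ring, collapse = ","))
  }, "")
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feats, collapse = ",")), path)
  invisible(path)
}
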