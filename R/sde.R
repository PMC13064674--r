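# Weighted standard deviational ellipse: weighted mean centre, azimuth
# (clockwise from north), standard deviations along the rotated axes, area
# and oblateness (major/minor), plus centre-of-gravity shifts between epochs.

#' Weighted standard deviational ellipse
#'
#' Centre = weighted mean of the points. With deviations (dx, dy) about the
#' centre, the azimuth theta (clockwise from north, in \[0, 180)) satisfies
#' tan(theta) = (A + sqrt(A^2 + 4 C^2)) / (2 C), A = sum w dx^2 - sum w dy^2,
#' C = sum w dx dy; the axis standard deviations are
#' sigma_x = sqrt(sum w (dx cos(theta) - dy sin(theta))^2 / sum w) and
#' sigma_y = sqrt(sum w (dx sin(theta) + dy cos(theta))^2 / sum w);
#' the ellipse area is pi * sigma_x * sigma_y. Axis lengths are one standard
#' deviation (`scale = 1`); pass `scale = 2` for the 2-sigma convention.
#'
#' @param x,y Projected point coordinates in metres.
#' @param w Non-negative weights with positive total (default equal).
#' @param scale Axis scale factor (1 = one standard deviation).
#' @return List of class `sde_params`: `centre` (x, y in m), `azimuth_deg`
#'   (clockwise from north, \[0, 180)), `sigma_x`, `sigma_y` (m, along the
#'   rotated major/minor directions), `major_km`, `minor_km`, `area_km2`,
#'   `oblateness` (major/minor), `degenerate` (TRUE if the points are
#'   collinear, minor axis 0).
#' @export
weighted_sde <- function(x, y, w = rep(1, length(x)), scale = 1) {
  if (length(x) < 3L) stop("need at least three points")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with positive total")
  cx <- sum(w * x) / sum(w)
  cy <- sum(w * y) / sum(w)
  dx <- x - cx; dy <- y - cy
  A <- sum(w * dx^2) - sum(w * dy^2)
  C <- sum(w * dx * dy)
  if (abs(C) < 1e-12 * max(sum(w * dx^2), sum(w * dy^2), 1)) {
    # axis-aligned: major along the larger marginal spread
    theta <- if (A >= 0) pi / 2 else 0   # east-west if x spreads more
  } else {
    theta <- atan((A + sqrt(A^2 + 4 * C^2)) / (2 * C))
  }
  # theta is measured clockwise from north; rotate deviations
  s1 <- sqrt(sum(w * (dx * cos(theta) - dy * sin(theta))^2) / sum(w))
  s2 <- sqrt(sum(w * (dx * sin(theta) + dy * cos(theta))^2) / sum(w))
  # s2 is the spread along the azimuth direction, s1 across it
  if (s2 >= s1) {
    major <- s2; minor <- s1
    az <- theta
  } else {
    major <- s1; minor <- s2
    az <- theta + pi / 2
  }
  az <- az %% pi
  major <- major * scale; minor <- minor * scale
  degenerate <- minor < 1e-9 * max(major, 1)
  structure(list(centre = c(x = cx, y = cy),
                 azimuth_deg = az * 180 / pi,
                 sigma_x = major, sigma_y = minor,
                 major_km = major / 1000, minor_km = minor / 1000,
                 area_km2 = pi * major * minor / 1e6,
                 oblateness = if (degenerate) Inf else major / minor,
                 degenerate = degenerate),
            class = "sde_params")
}

#' @export
print.sde_params <- function(x, ...) {
  cat(sprintf("SDE: centre (%.1f, %.1f) m, azimuth %.2f deg, axes %.3f/%.3f km, oblateness %.3f\n",
              x$centre[1], x$centre[2], x$azimuth_deg,
              x$major_km, x$minor_km, x$oblateness))
  invisible(x)
}

#' SDE of a per-unit surface
#'
#' Points are unit centroids weighted by the surface values (the standard
#' value-weighted reading for ESV/LERI ellipses).
#'
#' @param grid An `eval_grid`.
#' @param values Per-unit weights aligned with `grid`.
#' @param scale Axis scale factor.
#' @return An `sde_params`.
#' @export
sde_from_grid <- function(grid, values, scale = 1) {
  weighted_sde(grid$centroid_x, grid$centroid_y, values, scale = scale)
}

#' Centre-of-gravity shift between two ellipses
#'
#' @param a,b `sde_params` for the earlier and later epoch.
#' @return List with `distance_km` (Euclidean, projected) and `bearing_deg`
#'   (direction of movement, clockwise from north).
#' @export
centroid_shift <- function(a, b) {
  dx <- b$centre["x"] - a$centre["x"]
  dy <- b$centre["y"] - a$centre["y"]
  list(distance_km = unname(sqrt(dx^2 + dy^2)) / 1000,
       bearing_deg = unname((atan2(dx, dy) * 180 / pi) %% 360))
}

#' Ellipse outline as GeoJSON
#'
#' @param sde An `sde_params`.
#' @param path Output path.
#' @param segments Polygon segments.
#' @return `path`, invisibly.
#' @export
write_sde_geojson <- function(sde, path, segments = 64) {
  t <- seq(0, 2 * pi, length.out = segments + 1)
  az <- sde$azimuth_deg * pi / 180
  # major axis points along the azimuth (from north), minor across it
  ex <- sde$sigma_x * cos(t); ey <- sde$sigma_y * sin(t)
  px <- sde$centre["x"] + ex * sin(az) + ey * cos(az)
  py <- sde$centre["y"] + ex * cos(az) - ey * sin(az)
  ring <- paste(sprintf("[%.3f,%.3f]", px, py), collapse = ",")
  writeLines(sprintf(
    '{"type":"Feature","properties":{"azimuth_deg":%.4f,"oblateness":%.4f},"geometry":{"type":"Polygon","coordinates":[[%s]]}}',
    sde$azimuth_deg, sde$oblateness, ring), path)
  invisible(path)
}
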