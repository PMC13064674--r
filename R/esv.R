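# Equivalent-factor valuation: one dimensionless equivalent is worth 1/7 of
# the market value of the regional mean grain yield per hectare; per-class,
# per-service equivalents then monetize land-class areas.

#' The 11 ecosystem service functions
#' @return Character vector of service column names, in conventional order.
#' @export
service_names <- function() {
  c("food_production", "raw_material", "water_supply", "gas_regulation",
    "climate_regulation", "environment_purification", "water_regulation",
    "soil_conservation", "nutrient_cycling", "biodiversity",
    "aesthetic_landscape")
}

#' Read an equivalent-factor table
#'
#' Rows are land classes, columns the 11 service functions. All factors must
#' be non-negative; construction land may be all-zero.
#'
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @return Data.frame of class `equivalent_table` with a `class` column plus
#'   the 11 service columns.
#' @export
read_equivalent_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!identical(names(tab), c("class", service_names())))
    stop("equivalent table must have columns: class, ",
         paste(service_names(), collapse = ", "))
  if (any(tab[, -1] < 0)) stop("equivalent factors must be non-negative")
  class(tab) <- c("equivalent_table", "data.frame")
  tab
}

#' Packaged default equivalent-factor table
#' @return The table shipped in `inst/extdata/equivalent_factors.csv`.
#' @export
default_equivalent_table <- function() {
  read_equivalent_table(system.file("extdata", "equivalent_factors.csv",
                                    package = "esvrisk", mustWork = TRUE))
}

#' Economic value of one service equivalent
#'
#' The value of one dimensionless equivalent per hectare: regional mean grain
#' yield times grain price divided by the standard divisor of 7 (one seventh
#' of the market economic value of the mean grain output).
#'
#' @param grain_yield Mean grain yield, kg/ha.
#' @param grain_price Grain price, CNY/kg.
#' @param divisor Dimensionless divisor (default 7).
#' @return Value in CNY per hectare per equivalent.
#' @export
equivalent_value <- function(grain_yield, grain_price, divisor = 7) {
  if (grain_yield <= 0 || grain_price <= 0 || divisor <= 0)
    stop("all valuation inputs must be strictly positive")
  grain_yield * grain_price / divisor
}

#' Ecosystem service value by unit, class and service
#'
#' ESV = sum over classes i and services j of A_i x S_ij x unit value, where
#' A_i is the class area within each evaluation unit and S_ij the equivalent
#' factor. Per-unit densities are reported in 10^4 CNY per hectare of the
#' unit's valid area.
#'
#' @param raster A `land_raster`.
#' @param grid The `eval_grid` derived from it.
#' @param table An `equivalent_table` covering every class present.
#' @param unit_value CNY/ha per equivalent, from [equivalent_value()].
#' @return List of class `esv_result`: `per_unit` (data.frame with `unit_id`,
#'   `value_cny`, `density` in 10^4 CNY/ha), `by_class` and `by_service`
#'   (named CNY totals), `total` (CNY), and `unit_value`.
#' @export
esv <- function(raster, grid, table = default_equivalent_table(),
                unit_value) {
  present <- raster$legend[as.character(sort(unique(raster$cells[!is.na(raster$cells)])))]
  missing_cls <- setdiff(unname(present), table$class)
  if (length(missing_cls))
    stop("equivalent table is missing class(es): ",
         paste(missing_cls, collapse = ", "))
  areas <- class_area(raster, grid)                 # km^2, cols = class names
  a_ha <- as.matrix(areas[, -1, drop = FALSE]) * 100  # km^2 -> ha
  fac <- as.matrix(table[match(colnames(a_ha), table$class), -1, drop = FALSE])
  fac[is.na(fac)] <- 0
  # unit x class value (CNY): area_ha * (sum_j S_ij) * unit_value
  class_equiv <- rowSums(fac)
  val_uc <- sweep(a_ha, 2L, class_equiv, `*`) * unit_value
  per_unit_val <- rowSums(val_uc)
  area_ha_unit <- grid$area_km2 * 100
  per_unit <- data.frame(unit_id = grid$unit_id,
                         value_cny = per_unit_val,
                         density = per_unit_val / area_ha_unit / 1e4)
  by_class <- colSums(val_uc)
  by_service <- as.numeric(colSums(a_ha) %*% fac) * unit_value
  names(by_service) <- colnames(fac)
  structure(list(per_unit = per_unit,
                 by_class = by_class,
                 by_service = by_service,
                 total = sum(per_unit_val),
                 unit_value = unit_value),
            class = "esv_result")
}

#' @export
print.esv_result <- function(x, ...) {
  cat("esv_result: total", format(x$total, big.mark = ","), "CNY over",
      nrow(x$per_unit), "units\n")
  invisible(x)
}

#' Epoch-to-epoch ESV change
#'
#' @param results List of >= 2 `esv_result`s on the same evaluation grid
#'   (epoch order).
#' @return List with `delta_total`, `delta_by_class`, `delta_by_service`
#'   (consecutive epoch differences, later minus earlier) and `cumulative`
#'   (last epoch minus first) on the same breakdowns.
#' @export
esv_change <- function(results) {
  if (length(results) < 2L) stop("need at least two epochs")
  ids <- lapply(results, function(r) r$per_unit$unit_id)
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]])))
    stop("esv results are not on the same evaluation grid")
  n <- length(results)
  pairs <- Map(function(a, b) list(
    total = b$total - a$total,
    by_class = b$by_class - a$by_class,
    by_service = b$by_service - a$by_service
  ), results[-n], results[-1])
  list(delta_total = vapply(pairs, `[[`, 0, "total"),
       delta_by_class = vapply(pairs, `[[`, results[[1]]$by_class, "by_class"),
       delta_by_service = vapply(pairs, `[[`, results[[1]]$by_service, "by_service"),
       cumulative = list(
         total = results[[n]]$total - results[[1]]$total,
         by_class = results[[n]]$by_class - results[[1]]$by_class,
         by_service = results[[n]]$by_service - results[[1]]$by_service))
}
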