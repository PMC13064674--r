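# CA-Markov projection: a row-stochastic Markov matrix fitted from two epochs
# sets per-class area demands (quantity); cellular-automata allocation places
# them spatially by ranking cells on suitability plus Moore-neighborhood
# density of the target class (location); kappa validates against a held-out
# epoch.

#' Fit a Markov transition model from two epochs
#'
#' T_ij = (area mapped i -> j) / (area of i in the first epoch); classes
#' absent from the first epoch get identity rows.
#'
#' @param a,b Aligned `land_raster`s (earlier, later).
#' @param step_years Years between the two epochs (metadata).
#' @return List of class `transition_model`: `labels`, `T` (row-stochastic
#'   matrix), `step_years`.
#' @export
fit_markov <- function(a, b, step_years = 10) {
  m <- transition_matrix(a, b)
  rs <- rowSums(m)
  T <- unclass(m)
  for (i in seq_along(rs)) {
    if (rs[i] > 0) T[i, ] <- T[i, ] / rs[i]
    else { T[i, ] <- 0; T[i, i] <- 1 }
  }
  structure(list(labels = rownames(T), T = T, step_years = step_years),
            class = "transition_model")
}

#' Project class areas with the Markov model
#'
#' S_(t+n) = S_t %*% T^n; total area is conserved.
#'
#' @param s Named class-area vector aligned with the model's labels.
#' @param model A `transition_model`.
#' @param steps Number of Markov steps.
#' @return Projected class-area vector.
#' @export
markov_project <- function(s, model, steps = 1L) {
  if (length(s) != length(model$labels))
    stop("area vector does not match the model's classes")
  if (any(s < 0)) stop("negative class areas")
  v <- matrix(s, nrow = 1)
  for (k in seq_len(steps)) v <- v %*% model$T
  stats::setNames(as.numeric(v), model$labels)
}

#' Build per-class suitability surfaces from drivers
#'
#' Each named driver is min-max normalized; `direction = "decrease"` flips it
#' (high suitability where the driver is low, e.g. construction near roads).
#' An optional `cap` saturates the preference: values of the transformed
#' driver at or above `cap` are equally (fully) suitable, so e.g. forest
#' suitability increases with slope up to a cap and is flat beyond it. A
#' class's suitability is the weighted mean of its transformed drivers.
#' Constraint-masked cells (mask 0) get suitability 0 everywhere and never
#' convert.
#'
#' @param drivers Named list of `cont_raster`s.
#' @param rules Named list (one entry per class) of data.frame-like rules
#'   with columns `driver`, `direction` ("increase"/"decrease"), `weight`,
#'   and optionally `cap` (saturation point in (0, 1\]; `NA` = none).
#' @param constraint Optional 0/1 matrix; 0 forbids conversion.
#' @return List of class `suitability_stack`: `surfaces` (named list of
#'   matrices in \[0, 1\]) and `constraint`.
#' @export
build_suitability <- function(drivers, rules, constraint = NULL) {
  norm01 <- function(m) {
    r <- range(m, na.rm = TRUE)
    if (diff(r) == 0) return(m * 0 + 0.5)
    (m - r[1]) / diff(r)
  }
  surfaces <- lapply(rules, function(rl) {
    rl <- as.data.frame(rl)
    miss <- setdiff(rl$driver, names(drivers))
    if (length(miss))
      stop("rule names missing driver(s): ", paste(miss, collapse = ", "))
    acc <- NULL; wsum <- 0
    for (i in seq_len(nrow(rl))) {
      m <- norm01(drivers[[rl$driver[i]]]$cells)
      if (rl$direction[i] == "decrease") m <- 1 - m
      cap <- if ("cap" %in% names(rl)) rl$cap[i] else NA_real_
      if (!is.na(cap)) m <- pmin(m, cap) / cap
      acc <- if (is.null(acc)) m * rl$weight[i] else acc + m * rl$weight[i]
      wsum <- wsum + rl$weight[i]
    }
    s <- acc / wsum
    if (!is.null(constraint)) s <- s * (constraint != 0)
    s
  })
  structure(list(surfaces = surfaces, constraint = constraint),
            class = "suitability_stack")
}

#' CA allocation configuration
#'
#' @param radius Moore neighborhood radius (default 2, a 5x5 window).
#' @param iterations Allocation rounds per Markov step (default 10); demand
#'   deficits are spread over rounds so the neighborhood-density feedback can
#'   act between rounds.
#' @param suit_weight,density_weight Composite-score weights for suitability
#'   and neighborhood density (defaults 0.7/0.3).
#' @param seed Seed for the random tie-break key.
#' @return List of class `ca_config`.
#' @export
ca_config <- function(radius = 2L, iterations = 10L,
                      suit_weight = 0.7, density_weight = 0.3, seed = 1L) {
  if (radius < 1L) stop("radius must be at least 1")
  structure(list(radius = radius, iterations = iterations,
                 suit_weight = suit_weight, density_weight = density_weight,
                 seed = seed),
            class = "ca_config")
}

# fraction of cells of class `code` in the Moore neighborhood of each cell
moore_density <- function(cells, code, radius) {
  nr <- nrow(cells); nc <- ncol(cells)
  is_c <- matrix(as.numeric(!is.na(cells) & cells == code), nr, nc)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr == 0 && dc == 0) next
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    acc <- acc + is_c[ri, ci]
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Cellular-automata spatial allocation
#'
#' Converts cells toward the Markov-projected class demands: in each round
#' the deficit classes claim their highest-scoring convertible cells (score =
#' suit_weight x suitability + density_weight x Moore-neighborhood density of
#' the target class) from surplus classes, with a seeded random tie-break.
#' Constraint cells never convert. Final areas match the demands within one
#' cell per class whenever feasible; infeasible demands yield a partial
#' allocation with a warning.
#'
#' @param landuse Current `land_raster`.
#' @param model A `transition_model` (one step is applied to current areas).
#' @param suit A `suitability_stack` with one surface per class name.
#' @param cfg A [ca_config()].
#' @param steps Markov steps to project the demands forward.
#' @return Projected `land_raster`.
#' @export
ca_allocate <- function(landuse, model, suit, cfg = ca_config(), steps = 1L) {
  cells <- landuse$cells
  codes <- as.integer(names(landuse$legend))
  labels <- unname(landuse$legend)
  if (!identical(sort(labels), sort(model$labels)))
    stop("model classes do not match the raster legend")
  valid <- !is.na(cells)
  counts <- vapply(codes, function(cd) sum(cells[valid] == cd), 0L)
  names(counts) <- labels
  demand_area <- markov_project(counts[model$labels], model, steps = steps)
  # convert demands to integer cell counts, largest-remainder rounding
  d <- demand_area[labels]
  fl <- floor(d)
  extra <- sum(valid) - sum(fl)
  rem_order <- order(d - fl, decreasing = TRUE)
  fl[rem_order[seq_len(extra)]] <- fl[rem_order[seq_len(extra)]] + 1
  demand <- stats::setNames(as.integer(fl), labels)
  frozen <- if (!is.null(suit$constraint)) suit$constraint == 0 else
    matrix(FALSE, nrow(cells), ncol(cells))
  set.seed(cfg$seed)
  tiekey <- matrix(stats::runif(length(cells)), nrow(cells), ncol(cells))
  for (round in seq_len(cfg$iterations)) {
    cur <- vapply(codes, function(cd) sum(cells[valid] == cd), 0L)
    names(cur) <- labels
    deficit <- demand - cur
    if (all(abs(deficit) <= 1L)) break
    frac <- (cfg$iterations - round + 1)
    for (cl in labels[order(-deficit)]) {
      need <- deficit[cl]
      if (need <= 1L) next
      take_n <- ceiling(need / frac)
      code_cl <- codes[match(cl, labels)]
      dens <- moore_density(cells, code_cl, cfg$radius)
      score <- cfg$suit_weight * suit$surfaces[[cl]] +
        cfg$density_weight * dens + 1e-9 * tiekey
      # convertible: valid, not frozen, currently in a surplus class
      surplus_codes <- codes[deficit[labels] < 0]
      convertible <- valid & !frozen &
        matrix(cells %in% surplus_codes, nrow(cells))
      idx <- which(convertible)
      if (!length(idx)) next
      ranked <- idx[order(score[idx], decreasing = TRUE)]
      # walk the full ranking; skip cells whose source class may not shrink
      # further (never drain a class below its own demand)
      taken <- 0L
      for (t in ranked) {
        if (taken >= take_n) break
        src <- labels[match(cells[t], codes)]
        if (deficit[src] < 0L && deficit[cl] > 0L) {
          cells[t] <- code_cl
          deficit[src] <- deficit[src] + 1L
          deficit[cl] <- deficit[cl] - 1L
          taken <- taken + 1L
        }
      }
    }
  }
  final <- vapply(codes, function(cd) sum(cells[valid] == cd), 0L)
  names(final) <- labels
  if (any(abs(final - demand) > 1L))
    warning("infeasible demands: allocation differs from Markov demand by more than one cell for ",
            paste(labels[abs(final - demand) > 1L], collapse = ", "))
  land_raster(cells, cell_size = landuse$cell_size, origin = landuse$origin,
              legend = landuse$legend)
}

#' Cohen's kappa between two categorical rasters
#'
#' Chance-corrected cell-wise agreement from the confusion matrix of cells
#' valid in both rasters.
#'
#' @param reference,predicted Aligned `land_raster`s.
#' @return Kappa in \[-1, 1\]; defined as 1 when both maps are constant and
#'   identical (expected agreement 1).
#' @export
kappa_agreement <- function(reference, predicted) {
  if (!identical(dim(reference$cells), dim(predicted$cells)))
    stop("raster shape mismatch")
  ok <- !is.na(reference$cells) & !is.na(predicted$cells)
  codes <- as.integer(names(reference$legend))
  tab <- table(factor(reference$cells[ok], levels = codes),
               factor(predicted$cells[ok], levels = codes))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}
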