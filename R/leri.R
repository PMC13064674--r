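# Landscape ecological risk: per-unit, per-class landscape pattern indices
# (separation, dominance, fragmentation, disturbance, vulnerability, loss)
# aggregated to the unit-level risk index
#   LERI_k = sum_i (A_ki / A_k) * R_i
# with patches clipped at evaluation-unit boundaries (unit-local indices).

#' Landscape vulnerability ranks
#'
#' Expert ranks of each class's sensitivity to disturbance, highest to
#' lowest: unused 6, water 5, cultivated 4, grassland 3, forest 2,
#' construction 1. `normalized` divides by the rank total (21 for the
#' defaults) giving the vulnerability index V_i.
#'
#' @param rank Named positive integer vector (one entry per class).
#' @return List of class `vuln_ranks` with `rank` and `normalized`.
#' @export
vulnerability_ranks <- function(rank = c(cultivated = 4, forest = 2,
                                         grassland = 3, water = 5,
                                         construction = 1, unused = 6)) {
  if (any(rank <= 0) || any(rank != round(rank)))
    stop("ranks must be positive integers")
  structure(list(rank = rank, normalized = rank / sum(rank)),
            class = "vuln_ranks")
}

#' Risk index weights
#'
#' Disturbance weights a, b, c combine fragmentation, separation and
#' dominance (defaults 0.5/0.3/0.2); dominance weights m, n combine relative
#' density and relative coverage (defaults 0.6/0.4).
#'
#' @param a,b,c Disturbance weights, must sum to 1.
#' @param m,n Dominance weights, must sum to 1.
#' @return List of class `risk_weights`.
#' @export
risk_weights <- function(a = 0.5, b = 0.3, c = 0.2, m = 0.6, n = 0.4) {
  if (abs(a + b + c - 1) > 1e-9) stop("a + b + c must sum to 1")
  if (abs(m + n - 1) > 1e-9) stop("m + n must sum to 1")
  structure(list(a = a, b = b, c = c, m = m, n = n), class = "risk_weights")
}

#' Label connected patches in a logical mask
#'
#' Two-pass connected-component labelling (breadth-first flood fill) under
#' 4- or 8-connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 (rook) or 8 (queen).
#' @return Integer matrix of patch labels (0 outside the mask); the number of
#'   patches is `max(result)`.
#' @export
label_patches <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 4) list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
          else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                    c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cr <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (o in offs) {
        r2 <- cr + o[1]; c2 <- cc + o[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          idx <- (c2 - 1L) * nr + r2
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- nxt
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  lab
}

#' Patch count and class area within one evaluation unit
#'
#' @param raster A `land_raster`.
#' @param grid An `eval_grid` derived from it.
#' @param unit_id Unit to inspect.
#' @param class_code Land-class code.
#' @param connectivity Patch connectivity (4 or 8).
#' @return List with `n` (patch count, clipped at the unit boundary) and
#'   `area_km2`.
#' @export
patches <- function(raster, grid, unit_id, class_code, connectivity = 8) {
  uid <- unit_index(raster, grid)
  sel <- which(uid == unit_id, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(list(n = 0L, area_km2 = 0))
  rr <- range(sel[, 1]); cr <- range(sel[, 2])
  sub <- raster$cells[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  inunit <- uid[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE] == unit_id
  inunit[is.na(inunit)] <- FALSE
  mask <- !is.na(sub) & sub == class_code & inunit
  n <- max(label_patches(mask, connectivity))
  list(n = as.integer(n),
       area_km2 = sum(mask) * (raster$cell_size / 1000)^2)
}

#' Per-unit, per-class landscape indices and unit risk index
#'
#' For each evaluation unit (total valid area A, km^2) and each class present
#' in it (area A_i, patch count n_i counted unit-locally):
#' separation S_i = (A / (2 A_i)) sqrt(n_i / A); relative density
#' L_i = n_i / sum_j n_j; relative coverage P_i = A_i / A; dominance
#' T_i = m L_i + n P_i; fragmentation F_i = n_i / A_i; disturbance
#' D_i = a F_i + b S_i + c T_i; loss R_i = V_i D_i. The unit's risk index is
#' LERI_k = sum_i (A_i / A) R_i.
#'
#' @inheritParams patches
#' @param ranks A [vulnerability_ranks()].
#' @param weights A [risk_weights()].
#' @param connectivity Patch connectivity (default 8).
#' @return List of class `landscape_metrics`: `per_class` (data.frame with
#'   unit_id, class, n, area_km2, S, L, P, T, F, D, R) and `per_unit`
#'   (data.frame with unit_id, area_km2, leri).
#' @export
landscape_indices <- function(raster, grid, ranks = vulnerability_ranks(),
                              weights = risk_weights(), connectivity = 8) {
  present <- unname(raster$legend[as.character(sort(unique(raster$cells[!is.na(raster$cells)])))])
  norank <- setdiff(present, names(ranks$rank))
  if (length(norank))
    stop("no vulnerability rank for class(es): ", paste(norank, collapse = ", "))
  uid <- unit_index(raster, grid)
  codes <- as.integer(names(raster$legend))
  cls_names <- unname(raster$legend)
  cell_km2 <- (raster$cell_size / 1000)^2
  rows <- vector("list", nrow(grid))
  leri <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    id <- grid$unit_id[k]
    sel <- which(uid == id, arr.ind = TRUE)
    rr <- range(sel[, 1]); cr <- range(sel[, 2])
    sub <- raster$cells[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    inu <- uid[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE] == id
    inu[is.na(inu)] <- FALSE
    a_tot <- sum(inu) * cell_km2
    counts <- integer(0); areas <- numeric(0); who <- character(0)
    for (ci in seq_along(codes)) {
      mask <- inu & !is.na(sub) & sub == codes[ci]
      n_cells <- sum(mask)
      if (n_cells == 0L) next
      who <- c(who, cls_names[ci])
      counts <- c(counts, max(label_patches(mask, connectivity)))
      areas <- c(areas, n_cells * cell_km2)
    }
    s_i <- (a_tot / (2 * areas)) * sqrt(counts / a_tot)
    l_i <- counts / sum(counts)
    p_i <- areas / a_tot
    t_i <- weights$m * l_i + weights$n * p_i
    f_i <- counts / areas
    d_i <- weights$a * f_i + weights$b * s_i + weights$c * t_i
    v_i <- ranks$normalized[who]
    r_i <- v_i * d_i
    leri[k] <- sum((areas / a_tot) * r_i)
    rows[[k]] <- data.frame(unit_id = id, class = who, n = counts,
                            area_km2 = areas, S = s_i, L = l_i, P = p_i,
                            T = t_i, F = f_i, D = d_i, R = unname(r_i))
  }
  structure(list(per_class = do.call(rbind, rows),
                 per_unit = data.frame(unit_id = grid$unit_id,
                                       area_km2 = grid$area_km2,
                                       leri = leri)),
            class = "landscape_metrics")
}

#' Per-unit LERI surface
#'
#' @param metrics A `landscape_metrics` from [landscape_indices()].
#' @return Data.frame with `unit_id` and `leri`, the same per-unit schema as
#'   the ESV surface.
#' @export
leri_surface <- function(metrics) {
  metrics$per_unit[, c("unit_id", "leri")]
}
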