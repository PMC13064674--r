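# Bivariate spatial autocorrelation between two per-unit surfaces: global
# cross-Moran's I (the z-scored spatial cross-product under row-standardized
# contiguity weights) and its local form with permutation-based LISA typing.

#' Contiguity weights on an evaluation grid
#'
#' @param grid An `eval_grid` (>= 2 units).
#' @param scheme `"queen"` (edge or corner) or `"rook"` (edge only).
#' @param row_standardize Row-standardize the weights (default TRUE).
#' @return List of class `spatial_weights`: `neighbors` (list of integer
#'   indices into the grid's row order), `weights` (matching numeric lists),
#'   `scheme`, `n`. Units with no neighbor are flagged with a warning.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook"),
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(grid)
  if (n < 2L) stop("need at least two units")
  key <- grid$urow * (max(grid$ucol) + 2L) + grid$ucol
  lookup <- seq_len(n)
  names(lookup) <- key
  offs <- if (scheme == "rook") list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
          else list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                    c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  nbs <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- vapply(offs, function(o)
      (grid$urow[i] + o[1]) * (max(grid$ucol) + 2L) + (grid$ucol[i] + o[2]), 0)
    hit <- lookup[as.character(cand)]
    nbs[[i]] <- sort(unname(hit[!is.na(hit)]))
  }
  iso <- which(lengths(nbs) == 0L)
  if (length(iso))
    warning(length(iso), " isolated unit(s) with no neighbors")
  w <- lapply(nbs, function(nb) {
    if (!length(nb)) numeric(0)
    else if (row_standardize) rep(1 / length(nb), length(nb))
    else rep(1, length(nb))
  })
  structure(list(neighbors = nbs, weights = w, scheme = scheme, n = n,
                 row_standardized = row_standardize),
            class = "spatial_weights")
}

# population z-score
zscore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero variance")
  (x - mean(x)) / s
}

spatial_lag <- function(z, w) {
  vapply(seq_len(w$n), function(i) {
    if (!length(w$neighbors[[i]])) return(0)
    sum(w$weights[[i]] * z[w$neighbors[[i]]])
  }, 0)
}

#' Bivariate Moran's I with local LISA typing
#'
#' Global statistic: I = (1/n) sum_i z_x(i) * lag_i(z_y) under
#' row-standardized weights (the conventional cross-Moran; equal to the
#' univariate Moran's I of x when y = x). Local statistic per unit:
#' I_i = z_x(i) * lag_i(z_y). Significance by conditional randomization:
#' holding x fixed, y is randomly reassigned across units (seeded), and a
#' two-sided pseudo p-value is computed per unit. Significant units are typed
#' from the signs of z_x(i) and the lag of z_y: H-H, L-L, L-H (low x, high
#' lag) or H-L; others NS.
#'
#' @param x,y Per-unit numeric vectors aligned with the weights' unit order.
#' @param w A `spatial_weights`.
#' @param permutations Number of randomizations (0 disables inference; all
#'   units NS).
#' @param alpha Significance level for cluster typing.
#' @param seed Integer seed for the randomization.
#' @return List of class `bimoran_result`: `I`, `local` (local statistics),
#'   `pseudo_p`, `clusters` (factor with levels NS, H-H, L-L, L-H, H-L),
#'   `permutations`, `alpha`.
#' @export
bivariate_moran <- function(x, y, w, permutations = 999, alpha = 0.05,
                            seed = 1L) {
  if (length(x) != w$n || length(y) != w$n)
    stop("x and y must align with the weights' unit set")
  zx <- zscore(x); zy <- zscore(y)
  lag_y <- spatial_lag(zy, w)
  local <- zx * lag_y
  I <- mean(local)
  lev <- c("NS", "H-H", "L-L", "L-H", "H-L")
  clusters <- factor(rep("NS", w$n), levels = lev)
  pseudo_p <- rep(NA_real_, w$n)
  if (permutations > 0) {
    set.seed(seed)
    exceed <- integer(w$n)
    for (p in seq_len(permutations)) {
      zp <- zy[sample.int(w$n)]
      lp <- spatial_lag(zp, w)
      exceed <- exceed + (abs(zx * lp) >= abs(local))
    }
    pseudo_p <- (exceed + 1) / (permutations + 1)
    sig <- pseudo_p < alpha
    lab <- ifelse(zx >= 0,
                  ifelse(lag_y >= 0, "H-H", "H-L"),
                  ifelse(lag_y >= 0, "L-H", "L-L"))
    clusters[sig] <- lab[sig]
  }
  structure(list(I = I, local = local, pseudo_p = pseudo_p,
                 clusters = clusters, permutations = permutations,
                 alpha = alpha),
            class = "bimoran_result")
}

#' Literal printed-form bivariate Moran coefficient
#'
#' The printed normalization with an outer factor n and an (n - 1) * sum(W)
#' denominator, retained for comparison with the conventional estimator:
#' I = n * sum_ij W_ij z_x(i) z_y(j) / ((n - 1) * sum_ij W_ij).
#'
#' @inheritParams bivariate_moran
#' @return The literal-form coefficient (a scalar).
#' @export
bivariate_moran_literal <- function(x, y, w) {
  zx <- zscore(x); zy <- zscore(y)
  sw <- sum(unlist(w$weights))
  cross <- sum(zx * spatial_lag(zy, w))
  w$n * cross / ((w$n - 1) * sw)
}

#' @export
print.bimoran_result <- function(x, ...) {
  cat("bivariate Moran's I =", signif(x$I, 5), "(", x$permutations,
      "permutations );", sum(x$clusters != "NS"), "significant units\n")
  invisible(x)
}

#' LISA cluster-type area transitions between epochs
#'
#' @param clusters_a,clusters_b Per-unit cluster factors aligned with `grid`.
#' @param grid The shared `eval_grid`.
#' @return An `area_matrix` over the five cluster types (km^2).
#' @export
cluster_transitions <- function(clusters_a, clusters_b, grid) {
  label_transitions(as.character(clusters_a), as.character(clusters_b), grid,
                    levels = c("NS", "H-H", "L-L", "L-H", "H-L"))
}
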