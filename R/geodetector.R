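# Geographical detector: the q statistic q = 1 - SSW/SST measures how much of
# a response's spatial variance a stratification of a candidate driver
# explains; the interaction detector evaluates q on the cross-classification
# of two stratifications. Variances are population variances so SST = N * s2.

#' Stratify a per-unit driver
#'
#' Continuous drivers are binned by natural breaks (default, L = 5) or
#' quantiles; categorical drivers pass through unchanged. Strata emptied by
#' tied boundaries are merged with their lower neighbor with a warning.
#'
#' @param values Per-unit driver values.
#' @param method `"jenks"`, `"quantile"` or `"categorical"`.
#' @param L Number of strata for continuous methods.
#' @return Factor of stratum labels, one per unit.
#' @export
stratify <- function(values, method = c("jenks", "quantile", "categorical"),
                     L = 5) {
  method <- match.arg(method)
  if (method == "categorical") {
    f <- factor(values)
    if (nlevels(f) < 2L) stop("need at least two strata")
    return(droplevels(f))
  }
  if (L < 2L) stop("L must be at least 2")
  if (length(unique(values)) < L)
    stop("not enough distinct values for ", L, " strata")
  if (method == "jenks") {
    sch <- jenks_breaks(values, k = L, labels = paste0("s", seq_len(L)))
    f <- classify(values, sch)
  } else {
    qs <- unique(stats::quantile(values, probs = seq(0, 1, length.out = L + 1)))
    f <- cut(values, breaks = qs, include.lowest = TRUE,
             labels = paste0("s", seq_len(length(qs) - 1L)))
  }
  if (any(table(f) == 0L)) {
    warning("empty stratum merged with neighbor")
    f <- droplevels(f)
  }
  f
}

#' Factor-detector q statistic
#'
#' q = 1 - SSW/SST with SSW = sum_h N_h * s2_h and SST = N * s2
#' (population variances).
#'
#' @param y Per-unit response values.
#' @param strata Factor of stratum labels aligned with `y`.
#' @return List of class `q_result`: `q`, `SSW`, `SST`, and `strata_stats`
#'   (data.frame with stratum, N, mean, var).
#' @export
factor_q <- function(y, strata) {
  if (length(y) != length(strata)) stop("y and strata must align")
  strata <- droplevels(factor(strata))
  n <- length(y)
  sst <- n * mean((y - mean(y))^2)
  if (sst <= 0) stop("zero total variance in the response")
  st <- do.call(rbind, lapply(split(y, strata), function(v)
    data.frame(N = length(v), mean = mean(v), var = mean((v - mean(v))^2))))
  st <- data.frame(stratum = rownames(st), st, row.names = NULL)
  ssw <- sum(st$N * st$var)
  structure(list(q = 1 - ssw / sst, SSW = ssw, SST = sst,
                 strata_stats = st),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat("q =", signif(x$q, 4), "over", nrow(x$strata_stats), "strata\n")
  invisible(x)
}

#' Interaction-detector q
#'
#' q on the cross-classification of two stratifications, with the standard
#' enhancement label from comparing q(1 int 2) against q1, q2 and q1 + q2:
#' `nonlinear-weaken` (below both), `single-weaken` (between them),
#' `bi-enhance` (above both but at most their sum), `independent` (equal to
#' the sum, within tolerance) or `nonlinear-enhance` (above the sum).
#'
#' @param y Per-unit response values.
#' @param strata1,strata2 Stratum factors aligned with `y`.
#' @return A `q_result` with extra fields `q1`, `q2` and `interaction`.
#' @export
interaction_q <- function(y, strata1, strata2) {
  q1 <- factor_q(y, strata1)$q
  q2 <- factor_q(y, strata2)$q
  cross <- interaction(droplevels(factor(strata1)),
                       droplevels(factor(strata2)), drop = TRUE)
  res <- factor_q(y, cross)
  tol <- 1e-9
  qsum <- q1 + q2
  label <- if (res$q < min(q1, q2) - tol) "nonlinear-weaken"
    else if (res$q < max(q1, q2) - tol) "single-weaken"
    else if (abs(res$q - qsum) <= tol) "independent"
    else if (res$q > qsum + tol) "nonlinear-enhance"
    else "bi-enhance"
  res$q1 <- q1; res$q2 <- q2; res$interaction <- label
  res
}

#' Run the factor detector over a driver set
#'
#' @param y Per-unit response values.
#' @param drivers Named list (or data.frame) of per-unit driver values.
#' @param method Discretizer for continuous drivers; see [stratify()].
#' @param L Stratum count for continuous drivers.
#' @param categorical Names of drivers to treat as categorical.
#' @return Data.frame with one row per driver: driver, L (strata used), q,
#'   SSW, SST, sorted by decreasing q.
#' @export
geodetect <- function(y, drivers, method = "jenks", L = 5,
                      categorical = character(0)) {
  rows <- lapply(names(drivers), function(nm) {
    m <- if (nm %in% categorical) "categorical" else method
    s <- stratify(drivers[[nm]], method = m, L = L)
    r <- factor_q(y, s)
    data.frame(driver = nm, L = nlevels(droplevels(s)), q = r$q,
               SSW = r$SSW, SST = r$SST)
  })
  out <- do.call(rbind, rows)
  out[order(-out$q), ]
}

#' Pairwise interaction matrix
#'
#' @inheritParams geodetect
#' @return List with `q` (symmetric matrix of interaction q values, single-
#'   factor q on the diagonal) and `label` (matrix of enhancement labels).
#' @export
geodetect_interactions <- function(y, drivers, method = "jenks", L = 5,
                                   categorical = character(0)) {
  nms <- names(drivers)
  strat <- lapply(nms, function(nm)
    stratify(drivers[[nm]],
             method = if (nm %in% categorical) "categorical" else method,
             L = L))
  names(strat) <- nms
  k <- length(nms)
  qm <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  lm <- matrix(NA_character_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    qm[i, i] <- factor_q(y, strat[[i]])$q
    for (j in seq_len(k)) {
      if (j <= i) next
      r <- interaction_q(y, strat[[i]], strat[[j]])
      qm[i, j] <- qm[j, i] <- r$q
      lm[i, j] <- lm[j, i] <- r$interaction
    }
  }
  list(q = qm, label = lm)
}
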