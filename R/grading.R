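# Natural-breaks (Fisher-Jenks) grading of per-unit surfaces into five
# ordered classes, plus grade-area accounting between epochs.

#' Grade labels for the five-class scheme
#' @param k Number of grades.
#' @return Character vector of labels.
#' @export
grade_labels <- function(k = 5) {
  base <- c("extremely_low", "low", "medium", "high", "extremely_high")
  if (k == 5) base else paste0("g", seq_len(k))
}

#' Optimal natural-breaks classification
#'
#' Fisher-Jenks dynamic programme: partitions sorted values into `k`
#' contiguous classes minimizing the total within-class sum of squared
#' deviations.
#'
#' @param values Numeric vector (>= k distinct values).
#' @param k Number of classes (default 5).
#' @param labels Class labels, lowest first.
#' @return List of class `grade_scheme`: `breaks` (k + 1 ascending boundary
#'   values, first = min, last = max; intervals are half-open with the top
#'   interval closed), `labels`, `k`, and `ssd` (optimal within-class SSD).
#' @export
jenks_breaks <- function(values, k = 5, labels = grade_labels(k)) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (length(unique(x)) < k)
    stop("need at least k distinct values for k classes")
  if (length(labels) != k) stop("need one label per class")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ssd of x[i..j] from prefix sums
  seg_cost <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[m, j]: optimal cost of splitting x[1..j] into m classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)   # start index of the last class
  for (j in 1:n) { D[1, j] <- seg_cost(1, j); B[1, j] <- 1L }
  for (m in 2:k) {
    if (k < 2) break
    for (j in m:n) {
      cand_i <- m:j  # last class is x[i..j]
      costs <- D[m - 1, cand_i - 1L] +
        vapply(cand_i, function(i) seg_cost(i, j), 0)
      best <- which.min(costs)
      D[m, j] <- costs[best]
      B[m, j] <- cand_i[best]
    }
  }
  # back-track class boundaries
  starts <- integer(k)
  j <- n
  for (m in k:1) {
    starts[m] <- B[m, j]
    j <- starts[m] - 1L
  }
  breaks <- c(x[1], x[starts[-1]], x[n])
  structure(list(breaks = breaks, labels = labels, k = k, ssd = D[k, n]),
            class = "grade_scheme")
}

#' Fixed-break grade scheme
#'
#' @param breaks k + 1 strictly ascending boundary values.
#' @param labels Class labels.
#' @return A `grade_scheme`.
#' @export
grade_scheme <- function(breaks, labels = grade_labels(length(breaks) - 1L)) {
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly ascending")
  if (length(labels) != length(breaks) - 1L)
    stop("need one label per interval")
  structure(list(breaks = breaks, labels = labels,
                 k = length(labels), ssd = NA_real_),
            class = "grade_scheme")
}

#' Classify a surface with a grade scheme
#'
#' Value v falls in grade g iff breaks\[g\] <= v < breaks\[g + 1\]; the top
#' interval is closed. Values outside the break range are clamped to the
#' first/last grade with a warning.
#'
#' @param values Numeric vector.
#' @param scheme A `grade_scheme`.
#' @return Factor of grade labels (levels in scheme order).
#' @export
classify <- function(values, scheme) {
  b <- scheme$breaks
  out_of_range <- values < b[1] | values > b[length(b)]
  if (any(out_of_range, na.rm = TRUE))
    warning(sum(out_of_range, na.rm = TRUE),
            " value(s) outside the break range were clamped")
  idx <- findInterval(values, b, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), scheme$k)
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Grade-to-grade area transitions between epochs
#'
#' @param grades_a,grades_b Per-unit grade factors aligned with `grid`.
#' @param grid The shared `eval_grid`.
#' @return An `area_matrix` over grades (km^2) with attribute `prop_delta`,
#'   the per-grade area-proportion change in percent.
#' @export
grade_transitions <- function(grades_a, grades_b, grid) {
  if (!identical(levels(grades_a), levels(grades_b)))
    stop("grade levels differ between epochs")
  label_transitions(as.character(grades_a), as.character(grades_b), grid,
                    levels = levels(grades_a))
}
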