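#' Getis-Ord Gi* hotspot statistic on a grid
#'
#' For each cell i the local statistic is the z-score
#'
#'   Gi* = (sum_j w_ij x_j - Xbar W_i) /
#'         (S * sqrt((n * sum_j w_ij^2 - W_i^2) / (n - 1)))
#'
#' with W_i = sum_j w_ij, Xbar = sum_j x_j / n and
#' S = sqrt(sum_j x_j^2 / n - Xbar^2).  Weights are binary
#' fixed-distance-band: w_ij = 1 for every cell j whose center lies within
#' `radius` of cell i's center, including i itself.  A constant field
#' (S = 0) yields z = 0 everywhere by definition.
#'
#' Positive z marks hotspots (locally high values), negative z cold spots.
#'
#' @param grid a `density_grid`; the statistic is computed on `values`.
#' @param radius neighborhood radius in meters (at least the cell size).
#' @return object of class `gi_star` with matrices `z` and `bin` (factor
#'   levels from [confidence_bins()]), plus `radius`.
#' @export
gi_star <- function(grid, radius) {
  n <- grid$nrow * grid$ncol
  if (n < 2) stop("spec error: at least 2 cells required")
  if (radius < grid$cell_size)
    stop("spec error: radius must be at least the cell size")
  x <- grid$values
  nr <- grid$nrow; nc <- grid$ncol
  cs <- grid$cell_size
  ## offsets (di, dj) with center distance <= radius (self included)
  m <- floor(radius / cs)
  off <- expand.grid(di = -m:m, dj = -m:m)
  keep <- sqrt(off$di^2 + off$dj^2) * cs <= radius + 1e-9
  off <- off[keep, , drop = FALSE]
  wsum <- matrix(0, nr, nc)   # W_i = number of in-grid neighbors
  lsum <- matrix(0, nr, nc)   # sum_j w_ij x_j
  for (k in seq_len(nrow(off))) {
    di <- off$di[k]; dj <- off$dj[k]
    ri <- max(1, 1 - di):min(nr, nr - di)   # target rows with valid source
    cj <- max(1, 1 - dj):min(nc, nc - dj)
    wsum[ri, cj] <- wsum[ri, cj] + 1
    lsum[ri, cj] <- lsum[ri, cj] + x[ri + di, cj + dj]
  }
  xbar <- sum(x) / n
  s <- sqrt(max(sum(x^2) / n - xbar^2, 0))
  if (s == 0) {
    z <- matrix(0, nr, nc)
  } else {
    denom <- s * sqrt((n * wsum - wsum^2) / (n - 1))
    z <- (lsum - xbar * wsum) / denom
    z[denom == 0] <- 0
  }
  structure(list(z = z, bin = confidence_bins(z), radius = radius,
                 origin = grid$origin, cell_size = cs),
            class = "gi_star")
}

#' @export
print.gi_star <- function(x, ...) {
  tb <- table(x$bin)
  cat(sprintf("<gi_star> %d cells, radius %g m\n", length(x$z), x$radius))
  print(tb)
  invisible(x)
}

#' Confidence bins from Gi* z-scores
#'
#' Standard-normal cut-offs 1.645 / 1.960 / 2.576 map |z| to 90 / 95 / 99
#' percent confidence, with the sign separating hotspots from cold spots.
#' Non-finite z-scores bin as not significant, with a warning.
#'
#' @param z numeric vector or matrix of z-scores.
#' @return factor (matrix-shaped if the input is a matrix) with levels
#'   `cold99, cold95, cold90, ns, hot90, hot95, hot99`.
#' @export
confidence_bins <- function(z) {
  lv <- c("cold99", "cold95", "cold90", "ns", "hot90", "hot95", "hot99")
  zz <- z
  if (any(!is.finite(zz))) {
    warning("confidence_bins: non-finite z treated as not significant")
    zz[!is.finite(zz)] <- 0
  }
  a <- abs(zz)
  lvl <- ifelse(a >= 2.576, 3L, ifelse(a >= 1.960, 2L, ifelse(a >= 1.645, 1L, 0L)))
  code <- 4L + sign(zz) * lvl
  out <- factor(lv[code], levels = lv)
  if (is.matrix(z)) dim(out) <- dim(z)
  out
}

#' Natural-breaks (Fisher-Jenks) classification
#'
#' Finds the k-class partition of the sorted values minimizing the total
#' within-class sum of squared deviations, by exact dynamic programming.
#' Deterministic; requires at least k distinct values.
#'
#' @param values numeric vector.
#' @param k number of classes (at least 2).
#' @return numeric vector of k - 1 interior break values; each break is
#'   the maximum of its (lower) class, so values v with
#'   `breaks[m-1] < v <= breaks[m]` fall in class m.
#' @export
natural_breaks <- function(values, k) {
  if (k < 2) stop("classing error: k must be at least 2")
  v <- sort(values[is.finite(values)])
  n <- length(v)
  if (length(unique(v)) < k)
    stop("classing error: fewer than k distinct values")
  ## ssd[a, b] helpers via prefix sums
  cs1 <- cumsum(v); cs2 <- cumsum(v^2)
  ssd <- function(a, b) {  # within-class SSD of v[a..b]
    s1 <- cs1[b] - if (a > 1) cs1[a - 1] else 0
    s2 <- cs2[b] - if (a > 1) cs2[a - 1] else 0
    max(s2 - s1^2 / (b - a + 1), 0)
  }
  ## D[m, j]: optimal cost of splitting v[1..j] into m classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)  # last class start index
  for (j in 1:n) { D[1, j] <- ssd(1, j); B[1, j] <- 1L }
  for (m in 2:k) {
    for (j in m:n) {
      best <- Inf; barg <- m
      for (a in m:j) {
        cost <- D[m - 1, a - 1] + ssd(a, j)
        if (cost < best) { best <- cost; barg <- a }
      }
      D[m, j] <- best; B[m, j] <- barg
    }
  }
  ## backtrack class boundaries
  breaks <- numeric(k - 1)
  j <- n
  for (m in k:2) {
    a <- B[m, j]
    breaks[m - 1] <- v[a - 1]   # max of the class below
    j <- a - 1L
  }
  breaks
}

#' Assign values to classes given interior natural breaks
#'
#' @param values numeric vector or matrix.
#' @param breaks interior breaks from [natural_breaks()] (class maxima).
#' @param labels optional class labels (length `length(breaks) + 1`).
#' @return integer class indices 1..k, or a factor when `labels` given;
#'   shaped like the input.
#' @export
apply_breaks <- function(values, breaks, labels = NULL) {
  cls <- findInterval(values, breaks, left.open = TRUE) + 1L
  if (!is.null(labels)) {
    out <- factor(labels[cls], levels = labels)
  } else out <- cls
  if (is.matrix(values)) dim(out) <- dim(values)
  out
}
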