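#' Per-pixel canopy-cover trend analysis
#'
#' Forest degradation is flagged from a multi-year percent tree-canopy
#' series (e.g. annual vegetation-continuous-fields epochs) by fitting an
#' ordinary-least-squares line per pixel and testing the fitted total
#' change over the series span against an absolute threshold: a drop of
#' more than 10 percentage points marks the pixel degraded.
#'
#' Pixels with fewer than `min_obs` valid observations are returned as
#' `NA` rather than raising an error.  An optional canopy-range mask
#' restricts the analysis to pixels whose mean valid canopy lies within
#' `canopy_range` (default 30-80 percent, the band in which forests are
#' mapped); set `canopy_range = NULL` to disable.
#'
#' @param canopy numeric matrix (pixels x years) or 3-D array
#'   (rows x cols x years) of percent canopy cover, `NA` for nodata.
#' @param years strictly increasing integer vector, one per
#'   column/band (at least 3).
#' @param threshold total-change threshold in percentage points; pixels
#'   with fitted `total_change < threshold` are degraded (default -10).
#' @param canopy_range two numbers or `NULL`; see Details.
#' @param min_obs minimum valid observations per pixel (default 3).
#' @return list of class `canopy_trend` with elements `slope`
#'   (cover/year), `total_change` (slope times the span), `degraded`
#'   (logical), each shaped like one epoch of the input, plus `years`.
#' @export
pixel_trend <- function(canopy, years, threshold = -10,
                        canopy_range = c(30, 80), min_obs = 3L) {
  if (length(years) < 3) stop("spec error: at least 3 epochs required")
  if (any(diff(years) <= 0)) stop("spec error: years must be strictly increasing")
  arr3 <- length(dim(canopy)) == 3
  Y <- if (arr3) {
    d <- dim(canopy)
    if (d[3] != length(years)) stop("spec error: third dimension must match years")
    matrix(canopy, d[1] * d[2], d[3])
  } else {
    if (ncol(canopy) != length(years)) stop("spec error: columns must match years")
    canopy
  }
  ok <- is.finite(Y)
  rng <- range(Y[ok], na.rm = TRUE)
  if (length(rng) && (rng[1] < 0 || rng[2] > 100))
    stop("domain error: canopy cover must lie in [0, 100]")
  nobs <- rowSums(ok)
  valid <- nobs >= min_obs
  if (!is.null(canopy_range)) {
    mu <- rowMeans(Y, na.rm = TRUE)
    valid <- valid & mu >= canopy_range[1] & mu <= canopy_range[2]
  }
  t <- as.numeric(years)
  slope <- rep(NA_real_, nrow(Y))
  full <- valid & nobs == length(t)
  if (any(full)) {
    tc <- t - mean(t)
    slope[full] <- (Y[full, , drop = FALSE] %*% tc) / sum(tc^2)
  }
  partial <- which(valid & nobs < length(t))
  for (i in partial) {
    sel <- ok[i, ]
    ts <- t[sel]; ys <- Y[i, sel]
    tc <- ts - mean(ts)
    slope[i] <- sum(tc * ys) / sum(tc^2)
  }
  span <- t[length(t)] - t[1]
  total_change <- slope * span
  degraded <- !is.na(total_change) & total_change < threshold
  degraded[!valid] <- NA
  shape <- function(v) if (arr3) matrix(v, dim(canopy)[1], dim(canopy)[2]) else v
  structure(list(slope = shape(slope), total_change = shape(total_change),
                 degraded = shape(degraded), years = years,
                 threshold = threshold),
            class = "canopy_trend")
}

#' @export
print.canopy_trend <- function(x, ...) {
  n <- sum(!is.na(x$degraded))
  cat(sprintf("<canopy_trend> %d valid pixel(s), %d degraded (total change < %g pp) over %d-%d\n",
              n, sum(x$degraded, na.rm = TRUE), x$threshold,
              min(x$years), max(x$years)))
  invisible(x)
}

#' Forest land-use conversion between two epochs
#'
#' Cells that are forest in the reference epoch and non-forest in the later
#' epoch are labeled with the later epoch's land-use code; all other cells
#' are `NA`.
#'
#' @param landuse_t0,landuse_t1 aligned categorical rasters (integer
#'   matrices of the same dimensions).
#' @param forest_codes integer code(s) denoting forest in `landuse_t0`.
#' @return list with `transition` (matrix, `NA` except converted cells)
#'   and `counts` (named table of destination codes).
#' @export
detect_conversion <- function(landuse_t0, landuse_t1, forest_codes) {
  if (!identical(dim(landuse_t0), dim(landuse_t1)))
    stop("alignment error: rasters must share extent and resolution")
  converted <- landuse_t0 %in% forest_codes & !(landuse_t1 %in% forest_codes) &
    !is.na(landuse_t0) & !is.na(landuse_t1)
  converted <- matrix(converted, nrow(landuse_t0), ncol(landuse_t0))
  transition <- matrix(NA_integer_, nrow(landuse_t0), ncol(landuse_t0))
  transition[converted] <- landuse_t1[converted]
  counts <- table(transition[converted])
  list(transition = transition,
       counts = stats::setNames(as.integer(counts), names(counts)))
}
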