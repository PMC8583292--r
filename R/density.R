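#' Regular planar density grids
#'
#' A `density_grid` holds per-cell values on a regular grid: `origin` is
#' the lower-left corner (meters), `cell_size` the square cell edge, and
#' `values` an `nrow x ncol` matrix whose row index increases with y (cell
#' `[i, j]` has center `origin + cell_size * (j - 0.5, i - 0.5)`).
#'
#' @param origin numeric length-2, lower-left corner (x, y) in meters.
#' @param cell_size positive cell edge length in meters.
#' @param nrow,ncol grid dimensions.
#' @param values optional matrix of initial values (defaults to zeros).
#' @return a `density_grid`.
#' @export
density_grid <- function(origin, cell_size, nrow, ncol, values = NULL) {
  if (cell_size <= 0) stop("spec error: cell_size must be positive")
  if (nrow < 1 || ncol < 1) stop("spec error: empty grid")
  if (is.null(values)) values <- matrix(0, nrow, ncol)
  stopifnot(identical(dim(values), c(as.integer(nrow), as.integer(ncol))) ||
              all(dim(values) == c(nrow, ncol)))
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 values = values),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cell_size, x$origin[1], x$origin[2]))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %g, median %g, max %g; %d nonzero\n",
                min(v), stats::median(v), max(v), sum(v != 0)))
  invisible(x)
}

#' Cell-center coordinates of a grid
#' @param grid a `density_grid`.
#' @return list with vectors `x` (length ncol) and `y` (length nrow).
#' @export
grid_centers <- function(grid) {
  list(x = grid$origin[1] + grid$cell_size * (seq_len(grid$ncol) - 0.5),
       y = grid$origin[2] + grid$cell_size * (seq_len(grid$nrow) - 0.5))
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) && a$cell_size == b$cell_size &&
    a$nrow == b$nrow && a$ncol == b$ncol
}

#' Rasterize classified features to a density grid
#'
#' Per cell, the amount of features whose class is in `classes` — a point
#' count, exactly clipped line length (km), or exactly clipped polygon
#' area (km^2) — divided by the cell area in km^2.
#'
#' @param features a classified `eco_features` collection (with a `class`
#'   column unless `classes = NULL`).
#' @param grid a `density_grid` defining the target lattice.
#' @param mode `"count"`, `"length"` or `"area"`; defaults to the natural
#'   measure of the collection's geometry type.
#' @param classes degradation classes to include (default `"degraded"`);
#'   `NULL` includes every feature.
#' @return the grid with per-cell densities (per km^2) in `values`.
#' @export
rasterize_density <- function(features, grid,
                              mode = c("auto", "count", "length", "area"),
                              classes = "degraded") {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- switch(attr(features, "geom_type") %||% "point",
                   point = "count", line = "length", polygon = "area")
  if (!is.null(classes)) {
    if (!"class" %in% names(features))
      stop("named-attribute error: features lack a 'class' column")
    features <- features[as.character(features$class) %in% classes, , drop = FALSE]
  }
  cs <- grid$cell_size
  cell_area_km2 <- (cs / 1e3)^2
  acc <- matrix(0, grid$nrow, grid$ncol)
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  col_of <- function(x) pmin(pmax(floor((x - x0) / cs) + 1L, 1L), grid$ncol)
  row_of <- function(y) pmin(pmax(floor((y - y0) / cs) + 1L, 1L), grid$nrow)
  for (g in features$geometry) {
    if (mode == "count") {
      cx <- mean(g[, 1]); cy <- mean(g[, 2])
      i <- row_of(cy); j <- col_of(cx)
      acc[i, j] <- acc[i, j] + 1
    } else if (mode == "length") {
      for (s in seq_len(nrow(g) - 1L)) {
        p <- g[s, ]; q <- g[s + 1L, ]
        jr <- sort(col_of(c(p[1], q[1]))); ir <- sort(row_of(c(p[2], q[2])))
        for (i in ir[1]:ir[2]) for (j in jr[1]:jr[2]) {
          len <- clip_segment_rect_length(p, q, x0 + (j - 1) * cs, x0 + j * cs,
                                          y0 + (i - 1) * cs, y0 + i * cs)
          acc[i, j] <- acc[i, j] + len / 1e3
        }
      }
    } else {
      jr <- sort(col_of(range(g[, 1]))); ir <- sort(row_of(range(g[, 2])))
      for (i in ir[1]:ir[2]) for (j in jr[1]:jr[2]) {
        clp <- clip_polygon_rect(g, x0 + (j - 1) * cs, x0 + j * cs,
                                 y0 + (i - 1) * cs, y0 + i * cs)
        if (nrow(clp) >= 3)
          acc[i, j] <- acc[i, j] + polygon_area(clp) / 1e6
      }
    }
  }
  grid$values <- acc / cell_area_km2
  grid$mode <- mode
  grid
}

#' Classify densities into k ordinal classes
#'
#' Positive-density cells receive scores 1..k (1 very low .. 5 very high
#' for the default k = 5); cells with zero density (no ecosystem present)
#' score 0.  Quantile classing places equal numbers of positive cells per
#' class with ties broken toward the lower class; equal-interval classing
#' splits the positive range evenly, collapsing to class 1 when the range
#' is degenerate.
#'
#' @param grid a `density_grid` with densities in `values`.
#' @param k number of classes (default 5).
#' @param method `"quantile"` (default) or `"equal_interval"`.
#' @return the grid with an integer `scores` matrix added.
#' @export
classify_density <- function(grid, k = 5L, method = c("quantile", "equal_interval")) {
  method <- match.arg(method)
  if (k < 2) stop("spec error: k must be at least 2")
  v <- grid$values
  pos <- which(v > 0)
  scores <- matrix(0L, grid$nrow, grid$ncol)
  if (length(pos) == 0) {
    warning("classify_density: all-zero grid, all scores 0")
  } else {
    pv <- v[pos]
    if (method == "quantile") {
      brk <- stats::quantile(pv, probs = seq_len(k - 1) / k, names = FALSE, type = 7)
      ## ties toward the lower class: cells equal to a break stay below it
      scores[pos] <- 1L + findInterval(pv, brk, left.open = TRUE)
    } else {
      rng <- range(pv)
      if (diff(rng) == 0) {
        scores[pos] <- 1L   # degenerate range collapses to the lowest class
      } else {
        brk <- rng[1] + diff(rng) * seq_len(k - 1) / k
        scores[pos] <- 1L + findInterval(pv, brk, left.open = TRUE)
      }
    }
  }
  grid$scores <- scores
  grid$class_method <- method
  grid$k <- as.integer(k)
  grid
}

#' Cell-wise sum of scored density layers
#'
#' @param grids list of `density_grid`s sharing origin, cell size and
#'   shape, each carrying a `scores` matrix.
#' @return a `density_grid` whose `values` are the per-cell score sums
#'   (range 0 to 5 x number of layers).
#' @export
sum_layers <- function(grids) {
  if (length(grids) == 0) stop("spec error: no layers to sum")
  ref <- grids[[1]]
  total <- matrix(0, ref$nrow, ref$ncol)
  for (g in grids) {
    if (!same_geometry(ref, g))
      stop("alignment error: grids must share origin, cell size and shape")
    if (is.null(g$scores)) stop("spec error: layer lacks scores; run classify_density first")
    total <- total + g$scores
  }
  density_grid(ref$origin, ref$cell_size, ref$nrow, ref$ncol, values = total)
}
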