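#' Percentage of a class total, rounded half-up to 2 decimals
#'
#' Printed assessment tables round half-up; base `round()` rounds half to
#' even, so the rounding is explicit here.  Unrounded values are available
#' via `round_digits = NULL`.
#'
#' @param part class quantity, `0 <= part <= total`.
#' @param total grand total, strictly positive.
#' @param round_digits decimals to round to (default 2; `NULL` disables).
#' @return percentage `100 * part / total`.
#' @export
class_percentages <- function(part, total, round_digits = 2) {
  if (any(total <= 0)) stop("domain error: total must be positive")
  if (any(part < 0 | part > total))
    stop("domain error: part must lie in [0, total]")
  pct <- 100 * part / total
  if (is.null(round_digits)) pct else round_half_up(pct, round_digits)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-class summary of a classified feature collection
#'
#' Totals per degradation class in the collection's native unit (area in
#' km^2 for polygons, length in km for polylines, count for points), with
#' half-up-rounded percentages.
#'
#' @param features classified `eco_features` with a `class` column (or a
#'   `di_class` column, used as fallback).
#' @param unit `"area"`, `"length"` or `"count"`; defaults to the natural
#'   unit for the geometry type.
#' @return one-row data.frame: `natural`, `natural_pct`, `semi`,
#'   `semi_pct`, `degraded`, `degraded_pct`, `total`, `unit`.
#' @export
summarize_classes <- function(features, unit = c("auto", "area", "length", "count")) {
  unit <- match.arg(unit)
  if (unit == "auto")
    unit <- switch(attr(features, "geom_type") %||% "point",
                   polygon = "area", line = "length", point = "count")
  cls <- if ("class" %in% names(features)) features$class else features$di_class
  if (is.null(cls)) stop("named-attribute error: features lack a class column")
  if (nrow(features) == 0) {
    warning("summarize_classes: empty input, zero row")
    return(data.frame(natural = 0, natural_pct = NA, semi = 0, semi_pct = NA,
                      degraded = 0, degraded_pct = NA, total = 0, unit = unit))
  }
  q <- feature_measure(features, unit)
  tot <- sum(q)
  by_class <- vapply(degradation_classes(), function(cl)
    sum(q[as.character(cls) == cl]), 0)
  data.frame(natural = by_class[1],
             natural_pct = class_percentages(by_class[1], tot),
             semi = by_class[2],
             semi_pct = class_percentages(by_class[2], tot),
             degraded = by_class[3],
             degraded_pct = class_percentages(by_class[3], tot),
             total = tot, unit = unit, row.names = NULL)
}

#' Zonal classification of a combined-degradation grid by region polygons
#'
#' Per region polygon, the area (km^2) and share falling in each grid
#' class, using exact cell-rectangle x polygon intersection.  Cells
#' classed 0 (no ecosystem present / below the lowest break) are reported
#' under the first label.
#'
#' @param grid a `density_grid` whose `values` hold class indices (e.g.
#'   from [apply_breaks()] on a summed score layer).
#' @param regions polygon `eco_features` (any kind) or a list of polygon
#'   matrices; region names from a `name` column when present.
#' @param labels class labels, one per class index present (default
#'   `low`, `medium`, `high` for 3 classes).
#' @return data.frame: one row per region with `region`, per-class `_km2`
#'   and `_pct` columns and `total_km2`.
#' @export
zonal_summary <- function(grid, regions, labels = NULL) {
  geoms <- if (inherits(regions, "eco_features") || is.data.frame(regions))
    regions$geometry else regions
  rnames <- if (is.data.frame(regions) && "name" %in% names(regions))
    as.character(regions$name) else paste0("region_", seq_along(geoms))
  classes <- sort(unique(as.integer(grid$values[is.finite(grid$values)])))
  if (is.null(labels))
    labels <- if (length(classes) == 3) c("low", "medium", "high")
              else paste0("class_", classes)
  cs <- grid$cell_size
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  rows <- lapply(seq_along(geoms), function(r) {
    ring <- geoms[[r]]
    area_by_class <- stats::setNames(numeric(length(classes)), labels)
    jr <- pmin(pmax(floor((range(ring[, 1]) - x0) / cs) + 1L, 1L), grid$ncol)
    ir <- pmin(pmax(floor((range(ring[, 2]) - y0) / cs) + 1L, 1L), grid$nrow)
    disjoint <- max(ring[, 1]) < x0 || min(ring[, 1]) > x0 + grid$ncol * cs ||
      max(ring[, 2]) < y0 || min(ring[, 2]) > y0 + grid$nrow * cs
    if (!disjoint) {
      for (i in ir[1]:ir[2]) for (j in jr[1]:jr[2]) {
        clp <- clip_polygon_rect(ring, x0 + (j - 1) * cs, x0 + j * cs,
                                 y0 + (i - 1) * cs, y0 + i * cs)
        if (nrow(clp) >= 3) {
          cl <- match(as.integer(grid$values[i, j]), classes)
          if (!is.na(cl))
            area_by_class[cl] <- area_by_class[cl] + polygon_area(clp) / 1e6
        }
      }
    }
    tot <- sum(area_by_class)
    if (tot == 0)
      warning("zonal_summary: region '", rnames[r],
              "' does not intersect the grid; zero row")
    pct <- if (tot > 0) round_half_up(100 * area_by_class / tot, 1)
           else rep(NA_real_, length(area_by_class))
    out <- data.frame(region = rnames[r], stringsAsFactors = FALSE)
    for (k in seq_along(labels)) {
      out[[paste0(labels[k], "_km2")]] <- area_by_class[k]
      out[[paste0(labels[k], "_pct")]] <- pct[k]
    }
    out$total_km2 <- tot
    out
  })
  do.call(rbind, rows)
}
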