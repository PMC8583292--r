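#' Spatial feature collections
#'
#' An `eco_features` object is a plain `data.frame` carrying one spatial
#' feature per row: a `geometry` list-column of two-column coordinate
#' matrices (planar x/y, meters), an ecosystem `kind`, and whatever
#' per-feature criterion attributes the kind's scoring scheme needs.
#'
#' Geometry types by kind: polygons for `grassland`, `lake`, `coastal` and
#' `forest_mask`; polylines for `river`; points for `cave`.
#'
#' @param df data.frame of per-feature attributes (one row per feature).
#' @param geometry list of numeric matrices with columns x, y (meters).
#'   Point geometries are 1-row matrices; polygon rings need not repeat the
#'   first vertex.
#' @param kind ecosystem kind, one of [eco_kinds()].
#' @param crs character identifier of the planar, metric CRS the
#'   coordinates are expressed in (e.g. `"EPSG:3844"`). Geographic
#'   (longitude/latitude) coordinate systems are rejected throughout the
#'   package.
#' @return An `eco_features` data.frame.
#' @export
eco_features <- function(df, geometry, kind, crs = "local-metric") {
  kind <- match.arg(kind, eco_kinds())
  if (!is.list(geometry) || (nrow(df) != length(geometry)))
    stop("`geometry` must be a list with one matrix per row of `df`")
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2 || !is.numeric(g))
      stop("each geometry must be a numeric matrix with columns x, y")
    colnames(g) <- c("x", "y")
    g
  })
  gt <- geom_type_for(kind)
  n_min <- c(point = 1L, line = 2L, polygon = 3L)[[gt]]
  bad <- vapply(geometry, nrow, 1L) < n_min
  if (any(bad))
    stop(sprintf("geometry error: kind '%s' requires %s geometries (>= %d vertices)",
                 kind, gt, n_min))
  if (gt == "point" && any(vapply(geometry, nrow, 1L) != 1L))
    stop("geometry error: point features must have exactly one vertex")
  df$geometry <- geometry
  attr(df, "kind") <- kind
  attr(df, "geom_type") <- gt
  attr(df, "crs") <- crs
  class(df) <- c("eco_features", "data.frame")
  df
}

#' @rdname eco_features
#' @export
eco_kinds <- function() {
  c("grassland", "forest_mask", "lake", "coastal", "river", "cave")
}

geom_type_for <- function(kind) {
  switch(kind,
         grassland = , forest_mask = , lake = , coastal = "polygon",
         river = "line",
         cave = "point",
         stop("unknown ecosystem kind: ", kind))
}

#' @export
print.eco_features <- function(x, ...) {
  cat(sprintf("<eco_features> %d %s feature(s), kind '%s', crs '%s'\n",
              nrow(x), attr(x, "geom_type"), attr(x, "kind"), attr(x, "crs")))
  print.data.frame(utils::head(as.data.frame(x)[setdiff(names(x), "geometry")], 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
`[.eco_features` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "geometry" %in% names(out)) {
    attr(out, "kind") <- attr(x, "kind")
    attr(out, "geom_type") <- attr(x, "geom_type")
    attr(out, "crs") <- attr(x, "crs")
    class(out) <- c("eco_features", "data.frame")
  }
  out
}

## ---- planar geometry primitives -------------------------------------------
## sf/terra are not dependencies; the package only ever needs a handful of
## exact operations on axis-aligned cells, implemented here.

#' Polygon ring area (shoelace), in squared coordinate units
#' @param ring numeric matrix of vertices (columns x, y); closure optional.
#' @return nonnegative area.
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Polyline length in coordinate units
#' @param line numeric matrix of vertices (columns x, y).
#' @return total length.
#' @export
polyline_length <- function(line) {
  if (nrow(line) < 2) return(0)
  d <- diff(line)
  sum(sqrt(rowSums(d^2)))
}

## Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle.
## Returns a matrix of vertices (possibly 0 rows).
clip_polygon_rect <- function(ring, xmin, xmax, ymin, ymax) {
  pts <- ring
  for (edge in 1:4) {
    if (nrow(pts) == 0) return(pts)
    inside <- switch(edge,
                     pts[, 1] >= xmin, pts[, 1] <= xmax,
                     pts[, 2] >= ymin, pts[, 2] <= ymax)
    n <- nrow(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      jp <- if (i == 1L) n else i - 1L
      cur <- pts[i, ]; prev <- pts[jp, ]
      if (inside[i]) {
        if (!inside[jp]) out <- rbind(out, edge_intersect(prev, cur, edge, xmin, xmax, ymin, ymax))
        out <- rbind(out, cur)
      } else if (inside[jp]) {
        out <- rbind(out, edge_intersect(prev, cur, edge, xmin, xmax, ymin, ymax))
      }
    }
    pts <- out
  }
  pts
}

edge_intersect <- function(p, q, edge, xmin, xmax, ymin, ymax) {
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  t <- switch(edge,
              (xmin - p[1]) / dx, (xmax - p[1]) / dx,
              (ymin - p[2]) / dy, (ymax - p[2]) / dy)
  c(p[1] + t * dx, p[2] + t * dy)
}

## Liang-Barsky: length of the part of segment p->q inside a rectangle.
clip_segment_rect_length <- function(p, q, xmin, xmax, ymin, ymax) {
  dx <- q[1] - p[1]; dy <- q[2] - p[2]
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    pk <- switch(k, -dx, dx, -dy, dy)
    qk <- switch(k, p[1] - xmin, xmax - p[1], p[2] - ymin, ymax - p[2])
    if (pk == 0) {
      if (qk < 0) return(0)
    } else {
      r <- qk / pk
      if (pk < 0) { if (r > t1) return(0); if (r > t0) t0 <- r }
      else        { if (r < t0) return(0); if (r < t1) t1 <- r }
    }
  }
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

## Even-odd point-in-polygon test.
point_in_polygon <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]))
      inside <- !inside
    j <- i
  }
  inside
}

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx^2 + dy^2
  t <- if (l2 == 0) 0 else max(0, min(1, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Distance from a point to a feature geometry
#'
#' Zero for points inside a polygon; otherwise the minimum Euclidean
#' distance to the geometry's vertices/edges.
#'
#' @param px,py point coordinates (meters).
#' @param geom geometry matrix (columns x, y).
#' @param geom_type one of `"point"`, `"line"`, `"polygon"`.
#' @return distance in meters.
#' @export
dist_point_geometry <- function(px, py, geom, geom_type) {
  if (geom_type == "point")
    return(sqrt((px - geom[1, 1])^2 + (py - geom[1, 2])^2))
  if (geom_type == "polygon" && point_in_polygon(px, py, geom))
    return(0)
  n <- nrow(geom)
  idx <- if (geom_type == "polygon") c(seq_len(n), 1L) else seq_len(n)
  dmin <- Inf
  for (i in seq_len(length(idx) - 1L)) {
    a <- geom[idx[i], ]; b <- geom[idx[i + 1L], ]
    dmin <- min(dmin, dist_point_segment(px, py, a[1], a[2], b[1], b[2]))
  }
  dmin
}

#' Native measure of a feature: area (km^2), length (km) or count (1)
#' @param features an `eco_features` object.
#' @param unit one of `"area"`, `"length"`, `"count"`.
#' @return numeric vector, one value per feature.
#' @export
feature_measure <- function(features, unit = c("area", "length", "count")) {
  unit <- match.arg(unit)
  switch(unit,
         area   = vapply(features$geometry, polygon_area, 0) / 1e6,
         length = vapply(features$geometry, polyline_length, 0) / 1e3,
         count  = rep(1, nrow(features)))
}

#' Bounding box of a feature collection
#' @param features an `eco_features` object.
#' @return named numeric vector xmin, xmax, ymin, ymax.
#' @export
features_bbox <- function(features) {
  xs <- unlist(lapply(features$geometry, function(g) g[, 1]))
  ys <- unlist(lapply(features$geometry, function(g) g[, 2]))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}
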