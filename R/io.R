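#' Read / write feature collections as GeoJSON
#'
#' Features travel as a GeoJSON FeatureCollection with a named `crs`
#' member identifying the planar metric CRS.  Geographic (lon/lat) input
#' is rejected, not reprojected: files whose CRS is WGS84/CRS84/EPSG:4326,
#' or which carry no CRS member at all (GeoJSON's default is geographic),
#' raise an error.  Supported geometries: Point, LineString and
#' single-ring Polygon.
#'
#' `read_features` also checks that every attribute required by the kind's
#' bundled scoring scheme is present.
#'
#' @param path GeoJSON file path.
#' @param kind ecosystem kind, one of [eco_kinds()].
#' @param check_attributes validate scheme attributes (default TRUE; the
#'   forest mask kind has none).
#' @return an `eco_features` collection.
#' @export
read_features <- function(path, kind, check_attributes = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path)
  crs <- doc$crs$properties$name
  if (is.null(crs))
    stop("CRS error: file declares no named CRS; planar metric coordinates required")
  if (grepl("4326|CRS84|WGS ?84", crs, ignore.case = TRUE))
    stop("CRS error: geographic (lon/lat) coordinates are rejected; ",
         "supply a planar metric CRS")
  gt <- geom_type_for(kind)
  want_type <- c(point = "Point", line = "LineString", polygon = "Polygon")[[gt]]
  feats <- doc$features
  geometry <- vector("list", length(feats))
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, want_type))
      stop("geometry error: feature ", i, " is ", f$geometry$type,
           " but kind '", kind, "' requires ", want_type)
    co <- f$geometry$coordinates
    geometry[[i]] <- switch(gt,
      point = matrix(as.numeric(unlist(co)), 1, 2),
      line = do.call(rbind, lapply(co, function(p) as.numeric(unlist(p)))),
      polygon = {
        ring <- do.call(rbind, lapply(co[[1]], function(p) as.numeric(unlist(p))))
        if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
          ring <- ring[-nrow(ring), , drop = FALSE]
        ring
      })
    rows[[i]] <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
  }
  props <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(stats::setNames(lapply(props, function(p)
    unlist(lapply(rows, function(r) r[[p]] %||% NA))), props),
    stringsAsFactors = FALSE, optional = TRUE)
  if (length(feats) == 0) df <- data.frame()
  out <- eco_features(df, geometry, kind = kind, crs = crs)
  if (check_attributes && kind != "forest_mask") {
    need <- required_attributes(kind)
    missing <- setdiff(need, names(out))
    if (length(missing))
      stop("named-attribute error: kind '", kind, "' requires attribute(s) ",
           paste(sprintf("'%s'", missing), collapse = ", "))
  }
  out
}

required_attributes <- function(kind) {
  scheme_name <- switch(kind, grassland = "grassland", cave = "cave",
                        river = "river", lake = "lake",
                        coastal = "coastal_terrestrial", return(character(0)))
  vapply(eco_scheme(scheme_name)$criteria, `[[`, "", "attribute")
}

#' @param features an `eco_features` collection to write.
#' @rdname read_features
#' @export
write_features <- function(features, path) {
  gt <- attr(features, "geom_type")
  type <- c(point = "Point", line = "LineString", polygon = "Polygon")[[gt]]
  cols <- setdiff(names(features), "geometry")
  fl <- lapply(seq_len(nrow(features)), function(i) {
    g <- features$geometry[[i]]
    coords <- switch(gt,
      point = as.numeric(g[1, ]),
      line = lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ])),
      polygon = list(c(lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ])),
                       list(as.numeric(g[1, ])))))
    props <- lapply(cols, function(cl) {
      v <- features[[cl]][i]
      if (is.factor(v)) as.character(v) else v
    })
    names(props) <- cols
    list(type = "Feature",
         geometry = list(type = type, coordinates = coords),
         properties = props)
  })
  doc <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = attr(features, "crs"))),
              features = fl)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read / write a grid as an ESRI ASCII raster (.asc)
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of cell
#' values, top row first.
#'
#' @param path file path.
#' @return [read_grid()] returns a `density_grid`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  for (k in 1:6) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  ## .asc rows run top-down; internal storage has row index increasing with y
  m <- m[nr:1, , drop = FALSE]
  density_grid(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, nr, nc, values = m)
}

#' @param grid a `density_grid` (its `values` matrix is written).
#' @param nodata value standing in for `NA` cells (default -9999).
#' @rdname read_grid
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  m <- grid$values
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid$ncol), paste("nrows", grid$nrow),
               paste("xllcorner", grid$origin[1]),
               paste("yllcorner", grid$origin[2]),
               paste("cellsize", grid$cell_size),
               paste("NODATA_value", nodata)), con)
  for (i in grid$nrow:1)
    writeLines(paste(sprintf("%.12g", m[i, ]), collapse = " "), con)
  invisible(path)
}
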