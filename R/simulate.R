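#' Synthetic-landscape simulation spec
#'
#' The generator emulates the statistical structure the assessment
#' pipeline assumes: spatially clustered degraded features (so genuine
#' hotspots exist), per-criterion attributes spanning all three threshold
#' bands, and a controllable true-degradation prevalence per ecosystem.
#' Attribute generation is class-conditional: the hidden true class is
#' drawn first (Bernoulli at the kind's prevalence), then attributes are
#' drawn inside bands that guarantee that class, so prevalence is a direct
#' parameter.
#'
#' Every `simulate_*` function seeds its own RNG stream from
#' `seed` plus a fixed per-module offset, so identical spec + seed give
#' identical output.
#'
#' @param extent numeric length-4 `c(xmin, xmax, ymin, ymax)` in meters
#'   (default a 100 km square).
#' @param n_features named integer vector of feature counts per kind.
#' @param prevalence named numeric vector of true degraded fractions per
#'   kind, each in \[0, 1\].
#' @param cluster_count number of degradation cluster centers (0 disables
#'   clustering: degraded features placed uniformly).
#' @param cluster_sd Gaussian cluster spread in meters.
#' @param noise_sd canopy observation noise, percent-cover sd.
#' @param seed integer RNG seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(extent = c(0, 1e5, 0, 1e5),
                            n_features = c(grassland = 300, cave = 150,
                                           river = 200, lake = 200, coastal = 150),
                            prevalence = c(grassland = 0.3, cave = 0.1,
                                           river = 0.3, lake = 0.15,
                                           coastal = 0.3, forest = 0.2),
                            cluster_count = 3, cluster_sd = 5000,
                            noise_sd = 2, seed = 1L) {
  if (any(prevalence < 0 | prevalence > 1))
    stop("spec error: prevalence must lie in [0, 1]")
  if (cluster_sd <= 0) stop("spec error: cluster_sd must be positive")
  if (any(n_features < 0)) stop("spec error: n_features must be nonnegative")
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("spec error: degenerate extent")
  structure(list(extent = extent, n_features = n_features,
                 prevalence = prevalence, cluster_count = cluster_count,
                 cluster_sd = cluster_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

module_offsets <- c(grassland = 11L, cave = 23L, river = 37L, lake = 41L,
                    coastal = 53L, canopy = 67L, validation = 79L)

## degraded features cluster around Gaussian centers; natural ones are uniform
place_features <- function(n, degraded, spec) {
  ex <- spec$extent
  x <- stats::runif(n, ex[1], ex[2])
  y <- stats::runif(n, ex[3], ex[4])
  nd <- sum(degraded)
  if (nd > 0 && spec$cluster_count > 0) {
    cx <- stats::runif(spec$cluster_count, ex[1], ex[2])
    cy <- stats::runif(spec$cluster_count, ex[3], ex[4])
    pick <- sample.int(spec$cluster_count, nd, replace = TRUE)
    x[degraded] <- pmin(pmax(cx[pick] + stats::rnorm(nd, 0, spec$cluster_sd), ex[1]), ex[2])
    y[degraded] <- pmin(pmax(cy[pick] + stats::rnorm(nd, 0, spec$cluster_sd), ex[3]), ex[4])
  }
  cbind(x = x, y = y)
}

square_polys <- function(centers, side) {
  lapply(seq_len(nrow(centers)), function(i) {
    h <- side[i] / 2
    cx <- centers[i, 1]; cy <- centers[i, 2]
    cbind(x = c(cx - h, cx + h, cx + h, cx - h),
          y = c(cy - h, cy - h, cy + h, cy + h))
  })
}

## sample an attribute value uniformly inside a criterion's band interval
sample_in_band <- function(cr, band) {
  lo <- cr$domain[1]; hi <- cr$domain[2]
  has_abs <- !is.null(cr$transform) && cr$transform == "abs"
  if (has_abs) lo <- 0
  t1 <- cr$thresholds[1]; t2 <- cr$thresholds[2]
  eps <- 1e-6 * (hi - lo)
  iv <- if (cr$direction == "higher_is_worse") {
    switch(band + 1L, c(lo, t1 - eps), c(t1, t2), c(t2 + eps, hi))
  } else {
    switch(band + 1L, c(t2 + eps, hi), c(t1, t2), c(lo, t1 - eps))
  }
  v <- stats::runif(1, iv[1], iv[2])
  if (has_abs && stats::runif(1) < 0.5) v <- -v
  v
}

## random per-criterion bands whose weighted sum stays in the target class:
## start at the all-natural / all-degraded corner and random-walk criteria,
## keeping only moves that preserve the class
draw_bands <- function(scheme, degraded) {
  w <- vapply(scheme$criteria, `[[`, 0, "weight")
  bands <- rep(if (degraded) 2L else 0L, length(w))
  target <- if (degraded) "degraded" else "natural"
  for (it in seq_len(3L * length(w))) {
    k <- sample.int(length(w), 1)
    prop <- bands
    prop[k] <- sample(0:2, 1)
    if (as.character(classify_aggregate(sum(w * prop), scheme$cutpoints)) == target)
      bands <- prop
  }
  bands
}

#' Simulate grassland parcels with hidden true classes
#'
#' Parcels labeled truly degraded draw attributes that place their DI at
#' 65 or above (always with invasive or bare-soil cover in the degraded
#' band); truly natural parcels draw attributes keeping DI at or below
#' 30.  Degraded parcels cluster spatially.
#'
#' @param spec a [simulation_spec()].
#' @param n parcel count (default from `spec$n_features`).
#' @return grassland `eco_features` with the six criterion attributes and
#'   a hidden logical `true_degraded` column.
#' @export
simulate_grassland <- function(spec, n = spec$n_features[["grassland"]]) {
  set.seed(spec$seed + module_offsets[["grassland"]])
  prev <- spec$prevalence[["grassland"]]
  degraded <- stats::runif(n) < prev
  centers <- place_features(n, degraded, spec)
  side <- stats::runif(n, 400, 1200)
  geom <- square_polys(centers, side)
  att <- matrix(0, n, 6, dimnames = list(NULL, grassland_attributes))
  crits <- grassland_criteria_specs()
  for (i in seq_len(n)) {
    if (degraded[i]) {
      bands <- sample(0:2, 6, replace = TRUE)
      heavy <- sample(5:6, 1)        # C5 or C6 degraded guarantees DI >= 100
      bands[heavy] <- 2L
    } else {
      bands <- c(sample(0:1, 3, replace = TRUE), 0L, 0L, 0L)  # DI <= 30
    }
    for (k in 1:6) att[i, k] <- sample_in_band(crits[[k]], bands[k])
  }
  df <- as.data.frame(att)
  df$true_degraded <- degraded
  eco_features(df, geom, kind = "grassland")
}

grassland_criteria_specs <- function() {
  list(criterion_spec("C1", "dist_locality_km", c(2, 4), "lower_is_worse",
                      domain = c(0, 10)),
       criterion_spec("C2", "dist_sheepfold_km", c(0.5, 2), "lower_is_worse",
                      domain = c(0, 8)),
       criterion_spec("C3", "slope_deg", c(15, 30), "higher_is_worse",
                      domain = c(0, 60)),
       criterion_spec("C4", "livestock_dev_pct", c(10, 30), "higher_is_worse",
                      domain = c(-80, 80), transform = "abs"),
       criterion_spec("C5", "invasive_pct", c(5, 20), "higher_is_worse",
                      domain = c(0, 90)),
       criterion_spec("C6", "bare_soil_pct", c(5, 20), "higher_is_worse",
                      domain = c(0, 90)))
}

#' Simulate scored-ecosystem features (cave, river, lake, coastal)
#'
#' Draws hidden true classes at the kind's prevalence and class-conditional
#' attributes under the kind's bundled scoring scheme; truly degraded
#' features are guaranteed to classify degraded, truly natural ones
#' natural.
#'
#' @param spec a [simulation_spec()].
#' @param kind `"cave"`, `"river"`, `"lake"` or `"coastal"`.
#' @param n feature count (default from `spec$n_features`).
#' @return `eco_features` with scheme attributes and hidden
#'   `true_degraded`.
#' @export
simulate_features <- function(spec, kind = c("cave", "river", "lake", "coastal"),
                              n = spec$n_features[[kind]]) {
  kind <- match.arg(kind)
  set.seed(spec$seed + module_offsets[[kind]])
  scheme <- eco_scheme(if (kind == "coastal") "coastal_terrestrial" else kind)
  prev <- spec$prevalence[[kind]]
  degraded <- stats::runif(n) < prev
  centers <- place_features(n, degraded, spec)
  geom <- switch(kind,
                 cave = lapply(seq_len(n), function(i) centers[i, , drop = FALSE]),
                 river = lapply(seq_len(n), function(i) {
                   len <- stats::runif(1, 2000, 6000)
                   ang <- stats::runif(1, 0, pi)
                   mid <- centers[i, ] + stats::rnorm(2, 0, 200)
                   rbind(centers[i, ] - len / 2 * c(cos(ang), sin(ang)), mid,
                         centers[i, ] + len / 2 * c(cos(ang), sin(ang)))
                 }),
                 square_polys(centers, stats::runif(n, 500, 1500)))
  raw_mode <- all(vapply(scheme$criteria, `[[`, "", "mode") == "raw")
  att <- matrix(0, n, length(scheme$criteria),
                dimnames = list(NULL, vapply(scheme$criteria, `[[`, "", "attribute")))
  for (i in seq_len(n)) {
    if (raw_mode) {
      ## pre-aggregated form scores: draw a class-consistent total and split it
      total <- if (degraded[i]) stats::runif(1, scheme$cutpoints[2], 140)
               else stats::runif(1, 0, scheme$cutpoints[1])
      u <- stats::runif(1, 0.3, 0.7)
      att[i, ] <- c(total * u, total * (1 - u))
    } else {
      bands <- draw_bands(scheme, degraded[i])
      for (k in seq_along(scheme$criteria))
        att[i, k] <- sample_in_band(scheme$criteria[[k]], bands[k])
    }
  }
  df <- as.data.frame(att)
  df$true_degraded <- degraded
  eco_features(df, geom, kind = kind)
}

#' Simulate a multi-year canopy-cover raster series with known truth
#'
#' Truly degraded pixels follow a linear decline whose total drop exceeds
#' 10 percentage points (drawn uniformly in 12-25 pp); other pixels hold a
#' constant level drawn in 35-75 percent.  Gaussian observation noise of
#' sd `spec$noise_sd` is added everywhere.
#'
#' @param spec a [simulation_spec()].
#' @param years integer vector of at least 3 epochs.
#' @param nrow,ncol raster dimensions.
#' @return list with `canopy` (3-D array rows x cols x years), `years` and
#'   `truth` (logical matrix of truly degraded pixels).
#' @export
simulate_canopy_series <- function(spec, years = 2000:2013, nrow = 40, ncol = 40) {
  if (length(years) < 3) stop("spec error: at least 3 epochs required")
  set.seed(spec$seed + module_offsets[["canopy"]])
  npx <- nrow * ncol
  prev <- spec$prevalence[["forest"]]
  truth <- matrix(stats::runif(npx) < prev, nrow, ncol)
  span <- max(years) - min(years)
  frac <- (years - min(years)) / span
  level <- matrix(stats::runif(npx, 35, 75), nrow, ncol)
  drop <- matrix(stats::runif(npx, 12, 25), nrow, ncol)
  start <- pmin(level + drop / 2, 78)
  canopy <- array(0, c(nrow, ncol, length(years)))
  for (t in seq_along(years)) {
    mu <- ifelse(truth, start - drop * frac[t], level)
    canopy[, , t] <- pmin(pmax(mu + stats::rnorm(npx, 0, spec$noise_sd), 0), 100)
  }
  list(canopy = canopy, years = years, truth = truth)
}

#' Draw ground-truth validation points from simulated features
#'
#' Points are drawn uniformly over the feature extent and keep the hidden
#' true label of the nearest feature within the buffer radius; draws with
#' no feature inside the buffer are rejected until `n` points are
#' collected.
#'
#' @param features simulated `eco_features` with a `true_degraded` column.
#' @param spec a [simulation_spec()].
#' @param n number of validation points (default 100).
#' @param radius buffer radius in meters (default 300).
#' @return data.frame with `x`, `y` and binary `truth`.
#' @export
simulate_validation_truth <- function(features, spec, n = 100, radius = 300) {
  if (nrow(features) == 0) stop("empty-set error: no features to validate against")
  if (n <= 0) stop("empty-set error: at least one validation point required")
  if (!"true_degraded" %in% names(features))
    stop("named-attribute error: features lack 'true_degraded'")
  set.seed(spec$seed + module_offsets[["validation"]])
  bb <- features_bbox(features)
  gt <- attr(features, "geom_type")
  out <- matrix(numeric(0), ncol = 3)
  guard <- 0L
  while (nrow(out) < n && guard < 200L) {
    guard <- guard + 1L
    m <- 4L * n
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    for (p in seq_len(m)) {
      d <- vapply(features$geometry, function(g)
        dist_point_geometry(px[p], py[p], g, gt), 0)
      if (min(d) <= radius) {
        out <- rbind(out, c(px[p], py[p],
                            as.integer(features$true_degraded[which.min(d)])))
        if (nrow(out) >= n) break
      }
    }
  }
  if (nrow(out) < n)
    warning("simulate_validation_truth: only ", nrow(out), " of ", n,
            " points fell within ", radius, " m of a feature")
  data.frame(x = out[, 1], y = out[, 2], truth = as.integer(out[, 3]))
}

#' Simulate a full landscape: all ecosystems plus canopy series
#'
#' @param spec a [simulation_spec()].
#' @param years canopy epochs passed to [simulate_canopy_series()].
#' @return named list: grassland/cave/river/lake/coastal `eco_features`
#'   and `canopy` (the series list).
#' @export
simulate_landscape <- function(spec, years = 2000:2013) {
  list(grassland = simulate_grassland(spec),
       cave = simulate_features(spec, "cave"),
       river = simulate_features(spec, "river"),
       lake = simulate_features(spec, "lake"),
       coastal = simulate_features(spec, "coastal"),
       canopy = simulate_canopy_series(spec, years))
}
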