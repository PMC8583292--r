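#' Grassland degradation index (DI)
#'
#' Grassland condition is assessed on six criteria.  Each criterion is
#' banded into a class score (0 natural, 1 semi-degraded, 2 degraded) and
#' the scores are combined as a weighted sum
#'
#'   DI = 5 s1 + 20 s2 + 5 s3 + 10 s4 + 50 s5 + 100 s6
#'
#' with criteria:
#' \describe{
#'   \item{C1 `dist_locality_km`}{proximity to localities: >4 km natural,
#'     2-4 km semi-degraded, <2 km degraded}
#'   \item{C2 `dist_sheepfold_km`}{proximity to sheepfolds: >2 km natural,
#'     0.5-2 km semi-degraded, <0.5 km degraded}
#'   \item{C3 `slope_deg`}{slope: <15 deg natural, 15-30 semi, >30 degraded}
#'   \item{C4 `livestock_dev_pct`}{signed livestock-density deviation:
#'     |dev| < 10 natural, 10-30 semi, >30 degraded}
#'   \item{C5 `invasive_pct`}{invasive species cover: <5 natural, 5-20
#'     semi, >20 degraded}
#'   \item{C6 `bare_soil_pct`}{bare soil / erosion cover: same bands as C5}
#' }
#' Band boundaries fall in the middle (semi-degraded) band.  DI of at most
#' 30 is natural, 65 or more degraded, anything between semi-degraded.
#'
#' @name grassland_di
NULL

grassland_weights <- c(5, 20, 5, 10, 50, 100)

grassland_attributes <- c("dist_locality_km", "dist_sheepfold_km", "slope_deg",
                          "livestock_dev_pct", "invasive_pct", "bare_soil_pct")

#' Band one grassland criterion value into a class score
#'
#' @param value the raw criterion value (km, degrees or percent; C4 may be
#'   signed).
#' @param criterion criterion id `"C1"` .. `"C6"`.
#' @return integer score 0, 1 or 2.
#' @export
score_criterion <- function(value, criterion = paste0("C", 1:6)) {
  criterion <- match.arg(criterion)
  if (!is.finite(value)) stop("domain error: non-finite criterion value")
  if (criterion != "C4" && value < 0)
    stop("domain error: negative value for ", criterion)
  if (criterion == "C3" && (value < 0 || value > 90))
    stop("domain error: slope must be in [0, 90]")
  if (criterion %in% c("C5", "C6") && value > 100)
    stop("domain error: percent cover above 100")
  switch(criterion,
         C1 = if (value > 4) 0L else if (value >= 2) 1L else 2L,
         C2 = if (value > 2) 0L else if (value >= 0.5) 1L else 2L,
         C3 = if (value < 15) 0L else if (value <= 30) 1L else 2L,
         C4 = { a <- abs(value); if (a < 10) 0L else if (a <= 30) 1L else 2L },
         C5 = if (value < 5) 0L else if (value <= 20) 1L else 2L,
         C6 = if (value < 5) 0L else if (value <= 20) 1L else 2L)
}

#' Degradation index from six criterion scores
#'
#' @param scores integer vector of exactly six class scores (C1..C6 order),
#'   each 0, 1 or 2.
#' @return integer DI in \[0, 380\], a multiple of 5.
#' @export
compute_di <- function(scores) {
  if (length(scores) != 6)
    stop("domain error: exactly six criterion scores required")
  if (!all(scores %in% 0:2))
    stop("domain error: criterion scores must be 0, 1 or 2")
  as.integer(sum(grassland_weights * scores))
}

#' Degradation class from a DI value
#'
#' DI up to 30 is natural, 65 and above degraded, in between
#' semi-degraded.  (For valid score combinations DI is a multiple of 5, so
#' the 31-34 and 61-64 gaps are unreachable; they classify as
#' semi-degraded for robustness.)
#'
#' @param di nonnegative degradation index.
#' @return degradation class factor.
#' @export
classify_di <- function(di) {
  if (any(di < 0)) stop("domain error: negative DI")
  factor(ifelse(di <= 30, "natural",
                ifelse(di >= 65, "degraded", "semi-degraded")),
         levels = degradation_classes())
}

#' Score a grassland feature collection with the six-criterion DI
#'
#' Convenience wrapper adding per-criterion scores `s1`..`s6`, `di` and
#' `di_class` columns.
#'
#' @param features grassland `eco_features` (or data.frame) carrying the
#'   six attribute columns named in [grassland_di].
#' @return the input with score columns appended.
#' @export
score_grassland <- function(features) {
  missing <- setdiff(grassland_attributes, names(features))
  if (length(missing))
    stop("named-attribute error: missing attribute(s) ",
         paste(sprintf("'%s'", missing), collapse = ", "))
  sc <- matrix(0L, nrow(features), 6)
  for (k in 1:6)
    sc[, k] <- vapply(features[[grassland_attributes[k]]],
                      score_criterion, 0L, criterion = paste0("C", k))
  colnames(sc) <- paste0("s", 1:6)
  for (k in 1:6) features[[paste0("s", k)]] <- sc[, k]
  features$di <- as.integer(sc %*% grassland_weights)
  features$di_class <- classify_di(features$di)
  features
}
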