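#' Declarative weighted-score engine
#'
#' A `scoring_scheme` is an ordered list of criteria plus two aggregate
#' cut-points.  Each criterion either bands a raw attribute into class
#' scores 0 (natural) / 1 (semi-degraded) / 2 (degraded) using two
#' thresholds and a direction, or (mode `"raw"`) passes the attribute value
#' through unchanged.  The aggregate is the weighted sum of criterion
#' scores; the class is `natural` when the aggregate is at most the lower
#' cut-point, `degraded` when it is at least the upper cut-point, and
#' `semi-degraded` in between.
#'
#' Banding uses a closed middle interval: values equal to either threshold
#' fall in the semi-degraded band.
#'
#' @param name criterion label.
#' @param attribute name of the feature attribute the criterion reads.
#' @param thresholds two increasing numbers bounding the middle band
#'   (ignored for mode `"raw"`).
#' @param direction `"higher_is_worse"` (large values degraded) or
#'   `"lower_is_worse"` (small values degraded).
#' @param weight nonnegative weight in the aggregate sum.
#' @param mode `"band"` (default) or `"raw"` (score equals the attribute
#'   value, e.g. pre-aggregated cave impact forms).
#' @param domain two numbers delimiting the valid attribute range; used for
#'   validation and by the synthetic generator.
#' @param transform optional `"abs"` to band the absolute value (signed
#'   deviations such as livestock-density departure).
#' @return A `criterion_spec` list.
#' @export
criterion_spec <- function(name, attribute, thresholds = NULL,
                           direction = c("higher_is_worse", "lower_is_worse"),
                           weight = 1, mode = c("band", "raw"),
                           domain = NULL, transform = NULL) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) || weight < 0)
    stop("validation error: weight must be a single finite nonnegative number")
  if (mode == "band") {
    if (is.null(thresholds) || length(thresholds) != 2 || !all(is.finite(thresholds)))
      stop("validation error: band criteria need two finite thresholds")
    if (thresholds[1] >= thresholds[2])
      stop("validation error: thresholds must be strictly increasing, got (",
           thresholds[1], ", ", thresholds[2], ")")
  }
  if (!is.null(transform) && !identical(transform, "abs"))
    stop("validation error: unknown transform '", transform, "'")
  structure(list(name = name, attribute = attribute, thresholds = thresholds,
                 direction = direction, weight = weight, mode = mode,
                 domain = domain, transform = transform),
            class = "criterion_spec")
}

#' @param criteria list of [criterion_spec()] objects.
#' @param cutpoints two strictly increasing aggregate cut-points
#'   `c(natural_max, degraded_min)`.
#' @param kind ecosystem kind the scheme scores.
#' @param label human-readable scheme name.
#' @rdname criterion_spec
#' @export
scoring_scheme <- function(criteria, cutpoints, kind, label = kind) {
  if (length(criteria) < 1) stop("validation error: at least one criterion required")
  if (!all(vapply(criteria, inherits, TRUE, "criterion_spec")))
    stop("validation error: criteria must be criterion_spec objects")
  if (length(cutpoints) != 2 || !all(is.finite(cutpoints)) ||
      cutpoints[1] >= cutpoints[2])
    stop("validation error: cutpoints must be two strictly increasing numbers, got (",
         paste(cutpoints, collapse = ", "), ")")
  structure(list(criteria = criteria, cutpoints = as.numeric(cutpoints),
                 kind = kind, label = label, aggregation = "weighted_sum"),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> '%s' (%s): %d criteria, cut-points %s / %s\n",
              x$label, x$kind, length(x$criteria),
              format(x$cutpoints[1]), format(x$cutpoints[2])))
  for (cr in x$criteria)
    cat(sprintf("  %-28s w=%-6g %s %s\n", cr$name, cr$weight, cr$mode,
                if (cr$mode == "band")
                  sprintf("[%s] (%g, %g)", cr$direction, cr$thresholds[1], cr$thresholds[2])
                else ""))
  invisible(x)
}

#' Load / write a scoring scheme as a YAML document
#'
#' @param path file path of a YAML scheme document.
#' @return [load_scheme()] returns a validated `scoring_scheme`.
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  doc <- yaml::read_yaml(path)
  criteria <- lapply(doc$criteria, function(cr) {
    criterion_spec(name = cr$name, attribute = cr$attribute,
                   thresholds = if (!is.null(cr$thresholds)) as.numeric(cr$thresholds),
                   direction = cr$direction %||% "higher_is_worse",
                   weight = cr$weight %||% 1,
                   mode = cr$mode %||% "band",
                   domain = if (!is.null(cr$domain)) as.numeric(cr$domain),
                   transform = cr$transform)
  })
  scoring_scheme(criteria, as.numeric(doc$cutpoints), doc$kind,
                 label = doc$label %||% doc$kind)
}

#' @param scheme a `scoring_scheme`.
#' @rdname load_scheme
#' @export
write_scheme <- function(scheme, path) {
  doc <- list(kind = scheme$kind, label = scheme$label,
              aggregation = scheme$aggregation,
              cutpoints = scheme$cutpoints,
              criteria = lapply(scheme$criteria, function(cr)
                Filter(Negate(is.null),
                       cr[c("name", "attribute", "mode", "direction",
                            "thresholds", "weight", "domain", "transform")])))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled scoring schemes
#'
#' The package ships scheme configurations for all six assessed ecosystems
#' under `inst/schemes/`.  `eco_scheme()` loads one by name.
#'
#' @param name one of `"grassland"`, `"cave"`, `"river"`, `"lake"`,
#'   `"coastal_terrestrial"`, `"coastal_marine"`.
#' @return a `scoring_scheme`.
#' @export
eco_scheme <- function(name = c("grassland", "cave", "river", "lake",
                                "coastal_terrestrial", "coastal_marine")) {
  name <- match.arg(name)
  load_scheme(system.file("schemes", paste0(name, ".yaml"),
                          package = "ecodegrade", mustWork = TRUE))
}

## band a single value into 0/1/2 under the closed-middle convention
band_value <- function(value, criterion) {
  if (!is.null(criterion$transform) && criterion$transform == "abs")
    value <- abs(value)
  t1 <- criterion$thresholds[1]; t2 <- criterion$thresholds[2]
  if (criterion$direction == "higher_is_worse") {
    if (value < t1) 0L else if (value <= t2) 1L else 2L
  } else {
    if (value > t2) 0L else if (value >= t1) 1L else 2L
  }
}

#' Degradation class labels
#' @return ordered factor levels used throughout the package.
#' @export
degradation_classes <- function() c("natural", "semi-degraded", "degraded")

classify_aggregate <- function(aggregate, cutpoints) {
  cls <- ifelse(aggregate <= cutpoints[1], "natural",
                ifelse(aggregate >= cutpoints[2], "degraded", "semi-degraded"))
  factor(cls, levels = degradation_classes())
}

#' Apply a scoring scheme to one feature's attributes
#'
#' @param feature a one-row data.frame (or list) carrying every attribute
#'   the scheme names.
#' @param scheme a `scoring_scheme`.
#' @return list with `scores` (named per-criterion), `aggregate`
#'   (weighted sum) and `class` (degradation class factor).
#' @export
apply_scheme <- function(feature, scheme) {
  scores <- vapply(scheme$criteria, function(cr) {
    if (!cr$attribute %in% names(feature))
      stop("named-attribute error: missing attribute '", cr$attribute,
           "' required by criterion '", cr$name, "'")
    v <- feature[[cr$attribute]][1]
    if (!is.finite(v))
      stop("domain error: non-finite value for attribute '", cr$attribute, "'")
    if (!is.null(cr$domain) && (v < cr$domain[1] || v > cr$domain[2]))
      stop("domain error: attribute '", cr$attribute, "' = ", v,
           " outside declared domain [", cr$domain[1], ", ", cr$domain[2], "]")
    if (cr$mode == "raw") as.numeric(v) else as.numeric(band_value(v, cr))
  }, 0)
  names(scores) <- vapply(scheme$criteria, `[[`, "", "name")
  w <- vapply(scheme$criteria, `[[`, 0, "weight")
  aggregate <- sum(w * scores)
  list(scores = scores, aggregate = aggregate,
       class = classify_aggregate(aggregate, scheme$cutpoints))
}

#' Score and classify a homogeneous feature collection
#'
#' Adds `score` and `class` columns and tallies features per degradation
#' class.
#'
#' @param features an `eco_features` collection (or data.frame) whose rows
#'   all belong to the scheme's ecosystem kind.
#' @param scheme a `scoring_scheme`.
#' @return list with `features` (input plus `score`, `class`) and `tally`
#'   (named integer vector over the three classes).
#' @export
batch_score <- function(features, scheme) {
  n <- nrow(features)
  if (n == 0) {
    warning("batch_score: empty input, empty tally")
    tally <- stats::setNames(integer(3), degradation_classes())
    features$score <- numeric(0)
    features$class <- factor(character(0), levels = degradation_classes())
    return(list(features = features, tally = tally))
  }
  res <- lapply(seq_len(n), function(i) apply_scheme(features[i, , drop = FALSE], scheme))
  features$score <- vapply(res, `[[`, 0, "aggregate")
  features$class <- factor(vapply(res, function(r) as.character(r$class), ""),
                           levels = degradation_classes())
  tally <- table(features$class)
  list(features = features, tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Coastal class from an aggregate indicator score
#'
#' Terrestrial coast: scores of at most 4 are natural, 5-12 semi-degraded,
#' 13 and above degraded.  Marine coast: at most 5 natural, 6-15
#' semi-degraded, above 15 degraded.
#'
#' @param score nonnegative aggregate indicator sum.
#' @param zone `"terrestrial"` or `"marine"`.
#' @return degradation class factor.
#' @export
classify_coastal <- function(score, zone = c("terrestrial", "marine")) {
  zone <- match.arg(zone)
  if (any(score < 0)) stop("domain error: negative coastal score")
  cls <- if (zone == "terrestrial")
    ifelse(score <= 4, "natural", ifelse(score >= 13, "degraded", "semi-degraded"))
  else
    ifelse(score <= 5, "natural", ifelse(score > 15, "degraded", "semi-degraded"))
  factor(cls, levels = degradation_classes())
}
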