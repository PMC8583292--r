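#' Extract model class/score at validation points via a metric buffer
#'
#' Around each point a circular buffer of `radius` meters is examined; the
#' point receives the maximum degradation class and maximum aggregate
#' score among the scored features intersecting the buffer.  Points whose
#' buffer meets no feature are flagged and excluded from downstream
#' statistics.
#'
#' @param points two-column matrix or data.frame of planar x/y (meters).
#' @param features scored `eco_features` (with `score` and `class`).
#' @param radius buffer radius in meters (default 300).
#' @return data.frame with columns `x`, `y`, `matched`, `model_score`,
#'   `model_class` (`NA` where unmatched).
#' @export
extract_model_at_points <- function(points, features, radius = 300) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (!all(c("score", "class") %in% names(features)))
    stop("named-attribute error: features must carry 'score' and 'class'")
  gt <- attr(features, "geom_type")
  cls_num <- as.integer(factor(as.character(features$class),
                               levels = degradation_classes()))
  n <- nrow(pts)
  out <- data.frame(x = pts[, 1], y = pts[, 2], matched = FALSE,
                    model_score = NA_real_,
                    model_class = factor(rep(NA, n), levels = degradation_classes()))
  for (p in seq_len(n)) {
    hit <- which(vapply(features$geometry, function(g)
      dist_point_geometry(pts[p, 1], pts[p, 2], g, gt) <= radius, TRUE))
    if (length(hit)) {
      out$matched[p] <- TRUE
      out$model_score[p] <- max(features$score[hit])
      out$model_class[p] <- degradation_classes()[max(cls_num[hit])]
    }
  }
  if (!any(out$matched))
    stop("empty-validation error: no validation point buffer intersects any feature")
  out
}

#' Binary confusion matrix
#'
#' @param truth,predicted equal-length binary vectors (0/1 or logical).
#' @return 2x2 integer matrix with rows = truth (1, 0) and columns =
#'   predicted (1, 0): `tp fn / fp tn` counts summing to `length(truth)`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("alignment error: truth and predicted lengths differ")
  t1 <- as.integer(as.logical(truth)); p1 <- as.integer(as.logical(predicted))
  m <- matrix(c(sum(t1 == 1 & p1 == 1), sum(t1 == 1 & p1 == 0),
                sum(t1 == 0 & p1 == 1), sum(t1 == 0 & p1 == 0)),
              2, 2, byrow = TRUE,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  m
}

#' ROC curve and AUC from scores
#'
#' Sweeps thresholds down the distinct score values (equal scores form one
#' threshold step), accumulating true- and false-positive rates, and
#' integrates the area under the curve by the trapezoid rule — equal to
#' the normalized Mann-Whitney rank statistic with ties counted half.
#'
#' @param truth binary vector (1 = degraded); both classes must occur.
#' @param scores numeric ranking scores, larger = more degraded.
#' @return object of class `roc_curve`: data.frame-bearing list with
#'   `fpr`, `tpr` (starting at 0,0 and ending at 1,1) and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  t1 <- as.integer(as.logical(truth))
  if (length(t1) != length(scores))
    stop("alignment error: truth and scores lengths differ")
  np <- sum(t1 == 1); nn <- sum(t1 == 0)
  if (np == 0 || nn == 0)
    stop("undefined-AUC error: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- t1[o]
  last <- c(s[-1] != s[-length(s)], TRUE)   # end of each tie group
  tpr <- c(0, cumsum(y)[last] / np)
  fpr <- c(0, cumsum(1 - y)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc, n_pos = np, n_neg = nn),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False-positive rate",
                 ylab = "True-positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Validate a classified map against ground-truth points
#'
#' Runs the buffer extraction, reduces classes to binary (degraded vs not
#' degraded by default; `positive = "degraded_semi"` counts semi-degraded
#' as positive too), and reports the confusion matrix, ROC curve, AUC and
#' a strength verdict (strong/moderate at AUC of at least 0.8, weak
#' below).
#'
#' @param valset data.frame with columns `x`, `y`, `truth` (binary).
#' @param features scored `eco_features`.
#' @param radius buffer radius in meters (default 300).
#' @param positive `"degraded"` (default) or `"degraded_semi"`.
#' @return list: `n_used`, `confusion`, `roc` (a `roc_curve`), `auc`,
#'   `verdict`.
#' @export
validate_map <- function(valset, features, radius = 300,
                         positive = c("degraded", "degraded_semi")) {
  positive <- match.arg(positive)
  ext <- extract_model_at_points(valset[, c("x", "y")], features, radius)
  use <- ext$matched
  pos_classes <- if (positive == "degraded") "degraded" else
    c("degraded", "semi-degraded")
  pred <- as.character(ext$model_class[use]) %in% pos_classes
  truth <- as.integer(as.logical(valset$truth[use]))
  roc <- roc_auc(truth, ext$model_score[use])
  list(n_used = sum(use),
       confusion = confusion_matrix(truth, pred),
       roc = roc, auc = roc$auc,
       verdict = if (roc$auc >= 0.8) "strong/moderate" else "weak")
}
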