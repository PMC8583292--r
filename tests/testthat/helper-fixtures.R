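# shared fixtures built in code

# a minimal scored feature set: three unit squares (1 km2), one per class
three_class_squares <- function() {
  sq <- function(x0) cbind(x = c(x0, x0 + 1000, x0 + 1000, x0),
                           y = c(0, 0, 1000, 1000))
  f <- eco_features(data.frame(id = 1:3), list(sq(0), sq(2000), sq(4000)),
                    kind = "lake")
  f$class <- factor(degradation_classes(), levels = degradation_classes())
  f$score <- c(0, 8, 16)
  f
}

# independent brute-force Gi* (direct summation over all cell pairs)
gi_star_brute <- function(grid, radius) {
  ctr <- grid_centers(grid)
  xy <- expand.grid(y = ctr$y, x = ctr$x)   # column-major, matches as.vector
  x <- as.vector(grid$values)
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    w <- as.numeric(sqrt((xy$x - xy$x[i])^2 + (xy$y - xy$y[i])^2) <= radius + 1e-9)
    if (s == 0) { z[i] <- 0; next }
    z[i] <- (sum(w * x) - xbar * sum(w)) /
      (s * sqrt((n * sum(w^2) - sum(w)^2) / (n - 1)))
  }
  matrix(z, grid$nrow, grid$ncol)
}

# pairwise Mann-Whitney AUC oracle (ties counted half)
auc_pairwise <- function(truth, scores) {
  p <- scores[truth == 1]; q <- scores[truth == 0]
  u <- 0
  for (a in p) for (b in q) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(p) * length(q))
}

# exhaustive-search natural-breaks oracle: minimal within-class SSD over
# all ways to cut the sorted values into k contiguous classes
jenks_exhaustive <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf; best_breaks <- NULL
  for (cut in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, cut, n)
    cost <- sum(vapply(seq_len(k), function(m)
      ssd(v[(bounds[m] + 1):bounds[m + 1]]), 0))
    if (cost < best - 1e-12) {
      best <- cost
      best_breaks <- v[cut]
    }
  }
  list(breaks = best_breaks, cost = best)
}

jenks_cost <- function(values, breaks) {
  cls <- findInterval(sort(values), breaks, left.open = TRUE)
  sum(vapply(split(sort(values), cls), function(seg) sum((seg - mean(seg))^2), 0))
}
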