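test_that("confusion matrix counts match a per-item loop on random labels", {
  t0 <- c(1, 1, 0, 0); p0 <- c(1, 1, 0, 0)
  expect_equal(as.vector(confusion_matrix(t0, p0)), c(2, 0, 0, 2))
  expect_equal(as.vector(confusion_matrix(t0, 1 - p0)), c(0, 2, 2, 0))
  set.seed(3)
  tr <- rbinom(100, 1, 0.4); pr <- rbinom(100, 1, 0.5)
  m <- confusion_matrix(tr, pr)
  tp <- fn <- fp <- tn <- 0
  for (i in 1:100) {
    if (tr[i] == 1 && pr[i] == 1) tp <- tp + 1
    if (tr[i] == 1 && pr[i] == 0) fn <- fn + 1
    if (tr[i] == 0 && pr[i] == 1) fp <- fp + 1
    if (tr[i] == 0 && pr[i] == 0) tn <- tn + 1
  }
  expect_equal(as.vector(t(m)), c(tp, fn, fp, tn))
  expect_equal(sum(m), 100)
  expect_error(confusion_matrix(c(1, 0), c(1)), "alignment error")
})

test_that("AUC equals the pairwise Mann-Whitney statistic to 1e-12", {
  set.seed(29)
  for (rep in 1:5) {
    n <- 60
    tr <- rbinom(n, 1, 0.5)
    if (length(unique(tr)) < 2) next
    sc <- round(rnorm(n, mean = tr), 1)        # rounding creates ties
    expect_lt(abs(roc_auc(tr, sc)$auc - auc_pairwise(tr, sc)), 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  tr <- rbinom(80, 1, 0.5); sc <- rnorm(80, mean = tr)
  ref <- as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(tr, sc)$auc, ref, tolerance = 1e-10)
})

test_that("the ROC curve runs from (0,0) to (1,1) monotonically", {
  set.seed(33)
  tr <- rbinom(50, 1, 0.5); sc <- rnorm(50)
  r <- roc_auc(tr, sc)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("perfect separation gives AUC 1 and the null sits near 0.5", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(4, 3, 2, 1))$auc, 1)
  set.seed(37)
  tr <- rbinom(200, 1, 0.5); sc <- runif(200)    # independent of truth
  expect_gte(roc_auc(tr, sc)$auc, 0.42)
  expect_lte(roc_auc(tr, sc)$auc, 0.58)
})

test_that("AUC symmetries: complement under negation, invariance to monotone maps", {
  set.seed(41)
  tr <- rbinom(40, 1, 0.5); sc <- rnorm(40)      # continuous, tie-free
  a <- roc_auc(tr, sc)$auc
  expect_equal(a + roc_auc(tr, -sc)$auc, 1, tolerance = 1e-12)
  expect_equal(roc_auc(tr, exp(3 * sc))$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(tr, rank(sc))$auc, a, tolerance = 1e-12)
})

test_that("AUC rises monotonically with class-conditional separation", {
  set.seed(43)
  n <- 400
  tr <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  aucs <- vapply(c(0, 1, 2), function(d) roc_auc(tr, d * tr + noise)$auc, 0)
  expect_true(all(diff(aucs) > 0))
})

test_that("single-class truth is an error", {
  expect_error(roc_auc(c(1, 1, 1), c(1, 2, 3)), "undefined-AUC")
})

test_that("buffer extraction takes the worst class within radius", {
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  f <- eco_features(data.frame(id = 1), list(sq), kind = "lake")
  f$score <- 16
  f$class <- factor("degraded", levels = degradation_classes())
  # centered on the parcel
  inside <- extract_model_at_points(cbind(500, 500), f, radius = 300)
  expect_true(inside$matched)
  expect_equal(as.character(inside$model_class), "degraded")
  # 250 m outside the edge with a 300 m buffer still hits
  near <- extract_model_at_points(cbind(1250, 500), f, radius = 300)
  expect_true(near$matched)
  expect_equal(as.character(near$model_class), "degraded")
  # 350 m outside does not; all buffers empty is an error
  expect_error(extract_model_at_points(cbind(1350, 500), f, radius = 300),
               "empty-validation")
  # in a mixed set the worst class and max score win
  f2 <- three_class_squares()
  got <- extract_model_at_points(cbind(2990, 500), f2, radius = 3000)
  expect_equal(as.character(got$model_class), "degraded")
  expect_equal(got$model_score, 16)
})

test_that("validate_map reports confusion, AUC and a strength verdict", {
  spec <- simulation_spec(seed = 47, n_features = c(grassland = 150, cave = 0,
                                                    river = 0, lake = 0, coastal = 0))
  g <- simulate_grassland(spec)
  gs <- score_grassland(g)
  gs$score <- gs$di; gs$class <- gs$di_class
  vt <- simulate_validation_truth(g, spec, n = 80, radius = 1500)
  vm <- validate_map(vt, gs, radius = 1500)
  expect_equal(sum(vm$confusion), vm$n_used)
  expect_gte(vm$auc, 0.9)      # construction makes class follow truth
  expect_equal(vm$verdict, "strong/moderate")
})
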