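test_that("the generator is deterministic under a fixed seed", {
  spec <- simulation_spec(seed = 101, n_features = c(grassland = 40, cave = 30,
                                                     river = 20, lake = 20, coastal = 20))
  a <- simulate_landscape(spec, years = 2000:2005)
  b <- simulate_landscape(spec, years = 2000:2005)
  expect_identical(a, b)
  # and seed-stable on disk
  t1 <- withr::local_tempfile(fileext = ".geojson")
  t2 <- withr::local_tempfile(fileext = ".geojson")
  write_features(a$grassland, t1)
  write_features(b$grassland, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("prevalence 0 and 1 pin every parcel's DI to its class", {
  base <- simulation_spec(seed = 7)
  p0 <- base; p0$prevalence[["grassland"]] <- 0
  g0 <- score_grassland(simulate_grassland(p0, n = 200))
  expect_true(all(g0$di <= 30))
  p1 <- base; p1$prevalence[["grassland"]] <- 1
  g1 <- score_grassland(simulate_grassland(p1, n = 200))
  expect_true(all(g1$di >= 65))
  expect_error(simulation_spec(prevalence = c(grassland = 1.2)), "spec error")
})

test_that("empirical degraded fraction follows exact binomial sampling at the requested prevalence", {
  # coverage check: over 20 generator seeds the n = 500 empirical fraction
  # must fall inside the exact binomial 95% interval at least 17 times
  # (a single draw misses 5% of the time by construction)
  prev <- c(grassland = 0.4, cave = 0.1, river = 0.3, lake = 0.15,
            coastal = 0.3, forest = 0.2)
  ci <- stats::qbinom(c(0.025, 0.975), 500, 0.4) / 500
  inside <- vapply(1:20, function(sd) {
    g <- simulate_grassland(simulation_spec(seed = sd, prevalence = prev), n = 500)
    est <- mean(g$true_degraded)
    est >= ci[1] && est <= ci[2]
  }, TRUE)
  expect_gte(sum(inside), 17)
  # recovery tightens as n grows
  est <- vapply(c(200, 2000), function(n) {
    sp <- simulation_spec(seed = 13, prevalence = prev)
    mean(simulate_grassland(sp, n = n)$true_degraded)
  }, 0)
  expect_lt(abs(est[2] - 0.4), 0.025)
})

test_that("scored-kind generators guarantee class-consistent attributes", {
  spec <- simulation_spec(seed = 17, n_features = c(grassland = 0, cave = 60,
                                                    river = 60, lake = 60, coastal = 60))
  for (k in c("cave", "river", "lake", "coastal")) {
    f <- simulate_features(spec, k)
    sch <- eco_scheme(if (k == "coastal") "coastal_terrestrial" else k)
    bs <- batch_score(f, sch)
    expect_true(all((bs$features$class == "degraded") == f$true_degraded),
                label = k)
  }
})

test_that("canopy series: degraded pixels decline by more than 10 pp, others hold", {
  spec <- simulation_spec(seed = 19)
  spec$noise_sd <- 0
  cs <- simulate_canopy_series(spec, years = 2000:2013, nrow = 20, ncol = 20)
  tr <- pixel_trend(cs$canopy, cs$years, canopy_range = NULL)
  expect_true(all(tr$total_change[cs$truth] < -10))
  expect_equal(max(abs(tr$total_change[!cs$truth])), 0, tolerance = 1e-9)
  expect_error(simulate_canopy_series(spec, years = 2000:2001), "at least 3")
})

test_that("with sd-2 noise over 14 epochs the trend rule flags >= 95% of degraded pixels", {
  spec <- simulation_spec(seed = 23)       # noise_sd 2 by default
  cs <- simulate_canopy_series(spec, years = 2000:2013, nrow = 40, ncol = 40)
  tr <- pixel_trend(cs$canopy, cs$years, canopy_range = NULL)
  # normal-theory benchmark: the fitted total change is N(true_drop, se^2)
  # with se = 2 * span / sqrt(sum t_c^2) ~ 2.1 pp; the smallest drop (12)
  # sits ~0.95 sd past the threshold, so per-pixel power >= 0.82 and the
  # population mix (drops 12-25) pushes the detection rate well past 0.95
  expect_gte(mean(tr$degraded[cs$truth]), 0.95)
  expect_lte(mean(tr$degraded[!cs$truth]), 0.01)
})

test_that("validation truth points carry their source feature's hidden label", {
  spec <- simulation_spec(seed = 29, n_features = c(grassland = 100, cave = 0,
                                                    river = 0, lake = 0, coastal = 0))
  g <- simulate_grassland(spec)
  vt <- simulate_validation_truth(g, spec, n = 50, radius = 1000)
  expect_equal(nrow(vt), 50)
  expect_true(all(vt$truth %in% 0:1))
  gt <- attr(g, "geom_type")
  for (i in sample(nrow(vt), 10)) {
    d <- vapply(g$geometry, function(geom)
      dist_point_geometry(vt$x[i], vt$y[i], geom, gt), 0)
    expect_lte(min(d), 1000)
    expect_equal(vt$truth[i], as.integer(g$true_degraded[which.min(d)]))
  }
  expect_error(simulate_validation_truth(g[0, ], spec, n = 10), "empty-set")
  expect_error(simulate_validation_truth(g, spec, n = 0), "empty-set")
})

test_that("shuffled truth labels drive the downstream AUC to chance", {
  spec <- simulation_spec(seed = 31, n_features = c(grassland = 300, cave = 0,
                                                    river = 0, lake = 0, coastal = 0),
                          prevalence = c(grassland = 0.5, cave = 0, river = 0,
                                         lake = 0, coastal = 0, forest = 0.2))
  g <- simulate_grassland(spec)
  gs <- score_grassland(g)
  gs$score <- gs$di; gs$class <- gs$di_class
  vt <- simulate_validation_truth(g, spec, n = 100, radius = 1500)
  set.seed(33)
  vt$truth <- sample(vt$truth)
  vm <- validate_map(vt, gs, radius = 1500)
  expect_gte(vm$auc, 0.4)
  expect_lte(vm$auc, 0.6)
})
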