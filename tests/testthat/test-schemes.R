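test_that("bundled schemes carry the published weights and cut-points", {
  g <- eco_scheme("grassland")
  expect_equal(vapply(g$criteria, `[[`, 0, "weight"), c(5, 20, 5, 10, 50, 100))
  expect_equal(g$cutpoints, c(30, 65))
  cv <- eco_scheme("cave")
  expect_equal(cv$cutpoints, c(34, 85))
  expect_equal(length(eco_scheme("river")$criteria), 13L)
  expect_equal(sum(vapply(eco_scheme("river")$criteria, `[[`, 0, "weight")), 1,
               tolerance = 1e-6)
  expect_equal(length(eco_scheme("coastal_terrestrial")$criteria), 8L)
})

test_that("scheme validation rejects malformed configurations", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kind: lake", "cutpoints: [60.0, 30.0]", "criteria:",
               "- name: a", "  attribute: a", "  thresholds: [1.0, 2.0]",
               "  weight: 1.0"), tf)
  expect_error(load_scheme(tf), "strictly increasing")
  expect_error(criterion_spec("x", "x", thresholds = c(5, 2)), "validation error")
  expect_error(criterion_spec("x", "x", thresholds = c(1, 2), weight = -1),
               "validation error")
  expect_error(criterion_spec("x", "x", thresholds = c(1, 2),
                              direction = "sideways"))
})

test_that("schemes round-trip through YAML with thresholds intact", {
  for (nm in c("grassland", "cave", "river", "lake",
               "coastal_terrestrial", "coastal_marine")) {
    s <- eco_scheme(nm)
    tf <- withr::local_tempfile(fileext = ".yaml")
    write_scheme(s, tf)
    s2 <- load_scheme(tf)
    expect_equal(s2$cutpoints, s$cutpoints, label = nm)
    expect_equal(lapply(s2$criteria, `[[`, "thresholds"),
                 lapply(s$criteria, `[[`, "thresholds"), label = nm)
    expect_equal(vapply(s2$criteria, `[[`, 0, "weight"),
                 vapply(s$criteria, `[[`, 0, "weight"), label = nm)
  }
})

test_that("apply_scheme classifies cave aggregates at the 34 / 85 cut-points", {
  cv <- eco_scheme("cave")
  f <- data.frame(impact_score = 12, vulnerability_score = 8)   # aggregate 20
  r <- apply_scheme(f, cv)
  expect_equal(r$aggregate, 20)
  expect_equal(as.character(r$class), "natural")
  r2 <- apply_scheme(data.frame(impact_score = 50, vulnerability_score = 40), cv)
  expect_equal(as.character(r2$class), "degraded")
  r3 <- apply_scheme(data.frame(impact_score = 30, vulnerability_score = 30), cv)
  expect_equal(as.character(r3$class), "semi-degraded")
})

test_that("an identity scheme puts a middle-band feature at aggregate 1, semi", {
  s <- scoring_scheme(list(criterion_spec("only", "v", c(10, 20),
                                          "higher_is_worse", weight = 1)),
                      cutpoints = c(0, 2), kind = "lake")
  r <- apply_scheme(data.frame(v = 15), s)
  expect_equal(r$aggregate, 1)
  expect_equal(as.character(r$class), "semi-degraded")
})

test_that("apply_scheme reports missing and out-of-domain attributes by name", {
  g <- eco_scheme("grassland")
  f <- data.frame(dist_locality_km = 5, slope_deg = 3, livestock_dev_pct = 0,
                  invasive_pct = 1, bare_soil_pct = 1)
  expect_error(apply_scheme(f, g), "dist_sheepfold_km")
  f$dist_sheepfold_km <- 3
  f$invasive_pct <- 150
  expect_error(apply_scheme(f, g), "domain error.*invasive_pct")
})

test_that("coastal classification follows the printed terrestrial/marine bands", {
  expect_equal(as.character(classify_coastal(4, "terrestrial")), "natural")
  expect_equal(as.character(classify_coastal(5, "terrestrial")), "semi-degraded")
  expect_equal(as.character(classify_coastal(12, "terrestrial")), "semi-degraded")
  # 13 is unassigned by the printed bands; closed upward into degraded
  expect_equal(as.character(classify_coastal(13, "terrestrial")), "degraded")
  expect_equal(as.character(classify_coastal(5, "marine")), "natural")
  expect_equal(as.character(classify_coastal(15, "marine")), "semi-degraded")
  expect_equal(as.character(classify_coastal(16, "marine")), "degraded")
  expect_error(classify_coastal(-1, "terrestrial"), "domain error")
})

test_that("batch_score tallies match feature counts and classes", {
  f <- three_class_squares()
  f$wastewater_score <- c(10, 50, 90); f$recreation_score <- c(10, 50, 90)
  f$agriculture_score <- c(10, 50, 90); f$size_score <- c(10, 50, 90)
  f$transport_score <- c(10, 50, 90); f$industry_score <- c(10, 50, 90)
  f$cover_score <- c(10, 50, 90); f$vulnerability_score <- c(10, 50, 90)
  f$class <- NULL; f$score <- NULL
  bs <- batch_score(f, eco_scheme("lake"))
  expect_equal(sum(bs$tally), 3L)
  expect_equal(unname(bs$tally), c(1L, 1L, 1L))
  expect_equal(as.character(bs$features$class), degradation_classes())
  expect_warning(batch_score(f[0, ], eco_scheme("lake")), "empty")
})

test_that("zero-weight criteria never change the aggregate or class", {
  s <- eco_scheme("lake")
  s2 <- s
  s2$criteria <- c(s$criteria,
                   list(criterion_spec("noop", "wastewater_score", c(33, 66),
                                       "higher_is_worse", weight = 0)))
  set.seed(42)
  for (rep in 1:20) {
    f <- as.data.frame(as.list(stats::setNames(
      runif(8, 0, 100), vapply(s$criteria, `[[`, "", "attribute"))))
    r1 <- apply_scheme(f, s); r2 <- apply_scheme(f, s2)
    expect_equal(r2$aggregate, r1$aggregate)
    expect_equal(r2$class, r1$class)
  }
})

test_that("worsening any one criterion band never improves the class", {
  s <- eco_scheme("coastal_terrestrial")
  set.seed(7)
  attrs <- vapply(s$criteria, `[[`, "", "attribute")
  for (rep in 1:30) {
    f <- as.data.frame(as.list(stats::setNames(
      runif(8) * vapply(s$criteria, function(cr) cr$domain[2], 0), attrs)))
    base <- apply_scheme(f, s)
    k <- sample(8, 1)
    f2 <- f
    f2[[attrs[k]]] <- s$criteria[[k]]$domain[2]   # push to the worst band
    worse <- apply_scheme(f2, s)
    expect_gte(worse$aggregate, base$aggregate)
    expect_gte(as.integer(worse$class), as.integer(base$class))
  }
})

test_that("the DI expressed as a scoring scheme reproduces grassland_di on all 729 inputs", {
  g <- eco_scheme("grassland")
  # representative attribute values for each band of each criterion
  rep_vals <- list(
    dist_locality_km = c(5, 3, 1), dist_sheepfold_km = c(3, 1, 0.2),
    slope_deg = c(5, 20, 40), livestock_dev_pct = c(0, 20, 60),
    invasive_pct = c(1, 10, 50), bare_soil_pct = c(1, 10, 50))
  combos <- as.matrix(expand.grid(rep(list(1:3), 6)))
  for (i in seq_len(nrow(combos))) {
    f <- as.data.frame(as.list(stats::setNames(
      mapply(function(v, b) v[b], rep_vals, combos[i, ]), names(rep_vals))))
    r <- apply_scheme(f, g)
    scores <- combos[i, ] - 1L
    expect_equal(unname(r$scores), as.numeric(scores))
    expect_identical(as.integer(r$aggregate), compute_di(scores))
    expect_equal(r$class, classify_di(r$aggregate))
  }
})
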