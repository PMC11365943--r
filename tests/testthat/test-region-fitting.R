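test_that("equidistant subsampling spans the column with the target count", {
  expect_equal(equidistant_subsample(33), 1:33)
  expect_equal(equidistant_subsample(65), seq(1, 65, by = 2))
  idx <- equidistant_subsample(90)
  expect_length(idx, 33)
  expect_equal(idx[1], 1)
  expect_equal(idx[33], 90)
  expect_true(all(diff(idx) %in% 2:3))
  expect_false(anyDuplicated(idx) > 0)
  expect_error(equidistant_subsample(30), "33")
})

test_that("segmented fits recover exact piecewise data", {
  # single line, no breakpoints
  x <- 1:20
  y <- cbind(2 + 0.5 * x)
  m <- fit_segmented(y, x)
  expect_true(m$s < 1e-20)
  expect_true(m$saturated)
  expect_equal(unname(m$coefficients[2, 1]), 0.5, tolerance = 1e-10)

  # V-shape with the kink at a vertebra
  xv <- 1:33
  yv <- cbind(abs(xv - 17))
  mv <- fit_segmented(yv, xv, 17)
  expect_true(mv$s < 1e-16)
  expect_equal(unname(mv$coefficients[2, 1]), -1, tolerance = 1e-10)
  expect_equal(unname(mv$coefficients[2, 1] + mv$coefficients[3, 1]), 1,
               tolerance = 1e-10)

  expect_error(fit_segmented(yv, xv, c(17, 17)), "duplicate")
  expect_error(fit_segmented(yv, xv, 2), "fewer than 3")
})

test_that("continuous fits match a constrained least-squares oracle", {
  set.seed(14)
  for (i in 1:5) {
    x <- 1:18
    y <- rnorm(18)
    bp <- sort(sample(4:14, 2))
    if (diff(bp) < 3) next
    m <- fit_segmented(cbind(y), x, bp)
    expect_equal(m$s, segmented_oracle_rss(y, x, bp), tolerance = 1e-8)
  }
})

test_that("continuity never beats an unconstrained per-segment fit", {
  set.seed(15)
  x <- 1:24
  for (i in 1:5) {
    y <- rnorm(24, sd = 2)
    bp <- c(8, 16)
    m <- fit_segmented(cbind(y), x, bp)
    expect_true(m$s >= discontinuous_rss(y, x, bp) - 1e-10)
  }
})

test_that("the parameter count follows k = r p + p + r - 1", {
  set.seed(16)
  sc <- matrix(rnorm(33 * 3), 33, 3)
  m <- fit_segmented(sc, 1:33, c(7, 14, 21, 28))
  expect_equal(m$k, 5 * 3 + 3 + 5 - 1)   # r = 5, p = 3 -> 22
  for (r in c(1, 2, 6)) {
    bp <- if (r == 1) numeric(0) else round(seq(0, 33, length.out = r + 1))[2:r]
    for (p in 1:3) {
      mm <- fit_segmented(sc[, 1:p, drop = FALSE], 1:33, bp)
      expect_equal(mm$k, r * p + p + r - 1)
      expect_equal(mm$n, 33 * p)
    }
  }
})

test_that("exhaustive search enumerates the admissible configurations", {
  set.seed(17)
  sc <- matrix(rnorm(33 * 2), 33, 2)
  s1 <- search_models(sc, 1:33, 1)
  expect_length(s1$s, 1)
  expect_equal(s1$best$breakpoints, numeric(0))
  s2 <- search_models(sc, 1:33, 2, mode = "exhaustive")
  expect_length(s2$s, 28)
  expect_equal(sort(s2$positions[s2$configs[, 1]]), 3:30)
  expect_equal(n_breakpoint_configs(33, 2), 28)
  expect_equal(nrow(vertregions:::.enumerate_configs(20, 3)),
               n_breakpoint_configs(20, 3))
  expect_equal(n_breakpoint_configs(9, 4), 0)
  expect_error(search_models(sc[1:8, ], 1:8, 3), "no admissible")
})

test_that("heuristic search matches exhaustive enumeration on small instances", {
  set.seed(18)
  for (i in 1:4) {
    n <- sample(15:20, 1)
    sc <- matrix(rnorm(n * 2), n, 2)
    for (r in 2:4) {
      ex <- search_models(sc, 1:n, r, mode = "exhaustive")
      he <- search_models(sc, 1:n, r, mode = "heuristic", seed = i)
      expect_equal(min(he$s), min(ex$s), tolerance = 1e-10)
      expect_equal(he$best$breakpoints, ex$best$breakpoints)
    }
  }
})

test_that("the best RSS never increases with the region count", {
  set.seed(19)
  sc <- matrix(rnorm(24 * 2), 24, 2)
  sets <- fit_region_models(sc, 1:24, max_regions = 6, mode = "exhaustive")
  best <- vapply(sets, function(s) min(s$s), numeric(1))
  expect_true(all(diff(best) <= 1e-10))
})

test_that("BIC weights and region score follow the model-averaging rules", {
  w <- rep(0, 11)
  w[7] <- 0.4
  w[8] <- 0.6
  expect_equal(region_score(w), 7.6)
  w2 <- rep(0, 11); w2[5] <- 1
  expect_equal(region_score(w2), 5)
  expect_equal(region_score(rep(1 / 11, 11)), 6)
  expect_error(region_score(c(0.5, 0.2)), "sum to 1")

  set.seed(20)
  sc <- matrix(rnorm(33 * 2), 33, 2)
  cmp <- compare_models(fit_region_models(sc, 1:33, max_regions = 6))
  expect_equal(sum(cmp$weights), 1, tolerance = 1e-12)
  expect_equal(cmp$best_r, which.max(cmp$weights))
  expect_true(cmp$region_score >= 1 && cmp$region_score <= 6)
  expect_true(all(cmp$table$k == cmp$table$r * 2 + 2 + cmp$table$r - 1))
})

test_that("breakpoint estimates pool the top models by likelihood weight", {
  # hand-built archive: two equal-RSS models at breakpoints 10 and 12
  sc <- matrix(rnorm(40), 20, 2)
  set <- structure(list(
    best = fit_segmented(sc, 1:20, 10),
    configs = rbind(10L, 12L), s = c(1, 1), r = 2L,
    mode = "exhaustive", positions = 1:20), class = "model_set")
  est <- estimate_breakpoints(set, top_frac = 1)
  expect_equal(est$mean, 11)
  expect_equal(est$sd, 1)

  # single model: its breakpoints with zero spread
  set1 <- structure(list(best = set$best, configs = rbind(10L), s = 2,
                         r = 2L, mode = "exhaustive", positions = 1:20),
                    class = "model_set")
  est1 <- estimate_breakpoints(set1)
  expect_equal(est1$mean, 10)
  expect_equal(est1$sd, 0)
  expect_identical(attr(est1, "n_models"), 1L)

  # ceiling rule: 5% of 100 archived models is exactly 5
  set100 <- structure(list(best = set$best,
                           configs = matrix(sample(3:17, 100, TRUE)),
                           s = runif(100, 1, 2), r = 2L,
                           mode = "exhaustive", positions = 1:20),
                      class = "model_set")
  expect_identical(attr(estimate_breakpoints(set100), "n_models"), 5L)

  # strongly unequal RSS concentrates the weight on the better model
  set3 <- structure(list(best = set$best, configs = rbind(10L, 12L),
                         s = c(1, 10), r = 2L, mode = "exhaustive",
                         positions = 1:20), class = "model_set")
  est3 <- estimate_breakpoints(set3, n = 40, top_frac = 1)
  expect_true(est3$mean < 10.01)
})

test_that("fractional segment counts split spanning regions by vertebrae", {
  rr <- region_ranges(c(5, 10, 18, 21, 24), 27)
  expect_equal(unname(segment_region_counts(rr, 15)), c(2.625, 3.375))
  expect_equal(sum(segment_region_counts(rr, 15)), 6)

  # no spanning region: integer counts
  rr2 <- region_ranges(c(10, 20), 30)
  expect_equal(unname(segment_region_counts(rr2, 20)), c(2, 1))

  # a 10-vertebra region split 4/6
  rr3 <- region_ranges(numeric(0), 10)
  expect_equal(unname(segment_region_counts(rr3, 4)), c(0.4, 0.6))

  expect_error(segment_region_counts(rr2, 31), "outside")
  bad <- rr2
  bad$start[2] <- 13
  expect_error(segment_region_counts(bad, 20), "tile")
})

test_that("species aggregation averages weights and combines breakpoints", {
  mus <- rbind(10, 12)
  sds <- rbind(0, 0)
  comb <- vertregions:::.combine_breakpoints(mus, sds)
  expect_equal(comb$mean, 11)
  expect_equal(comb$sd, 1)
  # within-specimen spread enters through the law of total variance
  comb2 <- vertregions:::.combine_breakpoints(rbind(10, 12), rbind(2, 2))
  expect_equal(comb2$sd, sqrt(4 + 1))
})

test_that("fit_specimen recovers planted structure end to end", {
  cb <- column_blueprint(n = 40, r = 5, seed = 31)
  sim <- simulate_column(cb, seed = 32)
  col <- zscore_column(sim$column)
  fit <- fit_specimen(col, seed = 33)
  expect_equal(fit$r_star, 5)
  expect_true(mean(abs(fit$breakpoints$mean - sim$truth$breakpoints)) <= 1.5)
  expect_equal(max(fit$ranges$end), 40)
  expect_equal(sum(fit$segment_counts), fit$r_star)

  # species profile over one specimen equals the specimen fit
  prof <- species_profile(list(col), seed = 33)
  expect_equal(prof$r_star, fit$r_star)
  expect_equal(prof$segment_counts, fit$segment_counts)
  expect_equal(prof$weights, fit$comparison$weights, tolerance = 1e-12)

  # two identical specimens: species weights equal the shared vector
  col2 <- col
  col2$specimen <- "spA_2"
  prof2 <- species_profile(list(col, col2), seed = 33)
  expect_equal(prof2$weights, fit$comparison$weights, tolerance = 1e-12)
  expect_equal(prof2$breakpoints$mean, fit$breakpoints$mean,
               tolerance = 1e-10)
})
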