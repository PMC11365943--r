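# agreement between two labelings up to label permutation
perm_agreement <- function(a, b) {
  tb <- table(a, b)
  sum(apply(tb, 1, max)) / length(a)
}

test_that("spectral clustering separates well-spaced blobs and picks K", {
  set.seed(41)
  blobs2 <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 3),
                  matrix(rnorm(60, 5, 0.3), ncol = 3))
  truth2 <- rep(1:2, each = 20)
  cl2 <- spectral_cluster(blobs2, k_range = 2:8, seed = 1)
  expect_equal(cl2$K, 2)
  expect_equal(perm_agreement(cl2$labels, truth2), 1)

  blobs3 <- rbind(matrix(rnorm(45, 0, 0.3), ncol = 3),
                  matrix(rnorm(45, 6, 0.3), ncol = 3),
                  cbind(matrix(rnorm(30, -6, 0.3), ncol = 2),
                        rnorm(15, 6, 0.3)))
  truth3 <- rep(1:3, each = 15)
  cl3 <- spectral_cluster(blobs3, k_range = 2:8, seed = 7)
  expect_equal(cl3$K, 3)
  expect_equal(perm_agreement(cl3$labels, truth3), 1)

  # duplicating every point leaves K unchanged and co-clusters duplicates
  dup <- rbind(blobs2, blobs2)
  cld <- spectral_cluster(dup, k_range = 2:8, seed = 1)
  expect_equal(cld$K, 2)
  expect_equal(cld$labels[1:40], cld$labels[41:80])

  expect_error(spectral_cluster(matrix(0, 50, 3), k_range = 2:8),
               "identical")
  expect_error(spectral_cluster(blobs2[1:5, ], k_range = 2:8),
               "more observations")
})

test_that("clustering results are deterministic under a fixed seed", {
  set.seed(42)
  x <- rbind(matrix(rnorm(60, 0, 0.4), ncol = 3),
             matrix(rnorm(60, 4, 0.4), ncol = 3))
  a <- spectral_cluster(x, seed = 3)
  b <- spectral_cluster(x, seed = 3)
  expect_identical(a$labels, b$labels)
  expect_identical(a$K, b$K)
})

test_that("label smoothing absorbs isolated runs, anterior on ties", {
  expect_equal(smooth_labels(c("A", "A", "B", "A", "A")), rep("A", 5))
  expect_equal(smooth_labels(c("A", "A", "B", "B", "C", "C")),
               c("A", "A", "B", "B", "C", "C"))
  expect_equal(smooth_labels(c("A", "A", "A", "B", "C", "C", "C")),
               c("A", "A", "A", "A", "C", "C", "C"))  # tie -> anterior
  expect_equal(smooth_labels(c("B", "A", "A", "A")), rep("A", 4))
  expect_equal(smooth_labels("A"), "A")
})

test_that("species module maps retain majority modules and average bounds", {
  # one specimen: boundaries verbatim
  a1 <- c(rep("m1", 10), rep("m2", 10))
  map1 <- species_module_map(list(a1))
  expect_equal(map1$modules, c("m1", "m2"))
  expect_equal(map1$boundaries, 10)

  # equal counts, boundaries at 10 and 12 -> 11
  a2 <- c(rep("m1", 12), rep("m2", 8))
  map2 <- species_module_map(list(a1, a2))
  expect_equal(map2$boundaries, 11)

  # module in 1 of 3 specimens is dropped
  a3 <- c(rep("m1", 6), rep("m3", 6), rep("m2", 8))
  map3 <- species_module_map(list(a1, a2, a3))
  expect_equal(sort(map3$modules), c("m1", "m2"))

  # boundaries are averaged on the relative scale when counts differ
  b1 <- c(rep("m1", 5), rep("m2", 5))    # boundary at 0.5 of 10
  b2 <- c(rep("m1", 12), rep("m2", 8))   # boundary at 0.6 of 20
  mapb <- species_module_map(list(b1, b2), retained_count = 20)
  expect_equal(mapb$boundaries, 0.55 * 20)

  expect_error(species_module_map(list(c("a", "b"), c("c", "d"),
                                       c("e", "f"), c("g", "h"))),
               "half")
})

test_that("regions map to their modal module, anterior on ties", {
  labels <- c(rep("m1", 6), rep("m2", 6))
  rr <- region_ranges(c(4, 9), 12)
  expect_equal(regions_to_modules(rr, labels), c("m1", "m2", "m2"))
  # 3-of-5 majority
  rr2 <- region_ranges(c(5), 10)
  lab2 <- c("m1", "m1", "m1", "m2", "m2", rep("m2", 5))
  expect_equal(regions_to_modules(rr2, lab2), c("m1", "m2"))
  # 2/2 tie goes anterior with a warning
  rr3 <- region_ranges(numeric(0), 4)
  expect_warning(got <- regions_to_modules(rr3, c("m2", "m2", "m1", "m1")),
                 "tie")
  expect_equal(got, "m2")
  # never produces a module absent from the labels
  expect_true(all(regions_to_modules(rr, labels) %in% labels))
})

test_that("landmark offsets are signed vertebra differences", {
  col <- toy_column(toy_values(40), rib_end = 10, chevron_start = 25,
                    fluke_n = 3, rib_double = 6)
  off <- landmark_offsets(c(6, 12, 14), col)
  expect_equal(off$rib_transition, c(0, 6, 8))
  expect_equal(off$last_rib, c(-4, 2, 4))
  expect_equal(off$first_chevron, c(-19, -13, -11))

  # no double-headed ribs recorded: offset flagged missing
  col2 <- toy_column(toy_values(40), rib_end = 10, chevron_start = 25,
                     rib_double = 10)
  expect_true(all(is.na(landmark_offsets(c(6, 12), col2)$rib_transition)))
})

test_that("centrum ratios split compressed and flattened vertebrae", {
  vals <- toy_values(6)
  colnames(vals) <- default_schema()$name
  vals[, "Hc"] <- c(10, 10, 30, 30, 8, 8)
  vals[, "Wc"] <- c(10, 10, 20, 20, 16, 16)
  col <- toy_column(vals, rib_end = 2, chevron_start = 5)
  prof <- centrum_ratio_profile(col, labels = rep(c("a", "peduncle", "fluke"),
                                                  each = 2))
  expect_equal(prof$ratio, c(1, 1, 1.5, 1.5, 0.5, 0.5))
  expect_equal(prof$shape[3], "laterally_compressed")
  expect_equal(prof$shape[5], "flattened")
  mm <- prof$module_means
  expect_equal(mm$mean_ratio[mm$module == "peduncle"], 1.5)
  expect_true(mm$mean_ratio[mm$module == "peduncle"] >
                mm$mean_ratio[mm$module == "fluke"])
  vals[, "Wc"] <- 0
  expect_error(centrum_ratio_profile(toy_column(vals, chevron_start = 5)),
               "zero")
})

test_that("downstream outputs are invariant to label permutation", {
  labels <- c(rep("m1", 5), rep("m2", 7), rep("m3", 8))
  relabel <- c(m1 = "x9", m2 = "x1", m3 = "x5")
  perm <- unname(relabel[labels])
  rr <- region_ranges(c(6, 13), 20)
  expect_equal(unname(relabel[regions_to_modules(rr, labels)]),
               regions_to_modules(rr, perm))
  m1 <- species_module_map(list(labels, labels))
  m2 <- species_module_map(list(perm, perm))
  expect_equal(m1$boundaries, m2$boundaries)
  expect_equal(unname(relabel[m1$modules]), m2$modules)
})

test_that("planted module structure is recovered in a common morphospace", {
  # six well-separated clusters along pooled columns
  set.seed(55)
  n <- 36
  mb <- c(6, 12, 18, 24, 30)
  offsets <- matrix(rnorm(6 * 16, 0, 1), 6, 16) * 6
  sims <- lapply(1:2, function(i)
    simulate_column(column_blueprint(
      n = n, r = 4, chevron_start = 22, seed = 60,
      module_offsets = list(boundaries = mb, offsets = offsets)),
      species = "spA", specimen = paste0("spA_", i), seed = 70 + i))
  cols <- lapply(sims, function(s) zscore_column(s$column))
  ms <- common_morphospace(cols)
  mods <- cluster_modules(ms, k_range = 2:10, seed = 2)
  expect_equal(mods$K, 6)
  truth <- findInterval(1:n, mb + 0.5) + 1
  for (a in mods$assignments)
    expect_gte(perm_agreement(a, truth), 1 - 2 / n)  # boundaries within ~1
})
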