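test_that("read_columns parses a toy table and validates structure", {
  vals <- toy_values(3)
  col <- toy_column(vals, rib_end = 1, chevron_start = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_columns(list(col), f)
  got <- read_columns(f)
  expect_length(got, 1)
  expect_equal(got[[1]]$position, 1:3)
  expect_equal(unname(got[[1]]$values), unname(vals))
  expect_equal(got[[1]]$flags, col$flags)

  # position gap is reported with the missing position
  df <- utils::read.csv(f)
  df$position <- c(1, 2, 4)
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_columns(f), "missing 3")

  # duplicate (specimen, position)
  df$position <- c(1, 2, 2)
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_columns(f), "duplicate")

  # unknown status code
  df$position <- 1:3
  df$Hc_status <- c("measured", "shattered", "measured")
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_columns(f), "unknown status")
})

test_that("generated columns round-trip through the CSV dialect", {
  sim <- simulate_column(column_blueprint(n = 36, r = 4, seed = 9), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_columns(list(sim$column), f)
  got <- read_columns(f)[[1]]
  expect_equal(unname(got$values), unname(sim$column$values),
               tolerance = 1e-12)
  expect_identical(got$flags, sim$column$flags)
  expect_identical(unname(got$status), unname(sim$column$status))
})

test_that("absence rules zero linear values and interpolate angular ones", {
  vals <- toy_values(7)
  colnames(vals) <- default_schema()$name
  vals[, "Inp"] <- c(10, 20, 30, 99, 40, 50, 60)
  status <- matrix("measured", 7, 16,
                   dimnames = list(NULL, default_schema()$name))
  # interior absent neural spine at position 4, flanked by Inp 30 and 40
  status[4, c("Hns", "Wns", "Inp")] <- "absent"
  col <- toy_column(vals, rib_end = 2, chevron_start = 6, status = status)
  out <- apply_absence_rules(label_segments(col))
  expect_equal(unname(out$values[4, "Inp"]), 35)
  expect_equal(unname(out$values[4, "Hns"]), 0)
  expect_equal(unname(out$values[4, "Wns"]), 0)
  expect_identical(unname(out$status[4, "Inp"]), "absent")  # audit trail kept

  # terminal run copies the nearest bearing vertebra's angle
  status2 <- matrix("measured", 7, 16,
                    dimnames = list(NULL, default_schema()$name))
  status2[6:7, c("Wtp", "Htp", "Itp")] <- "absent"
  vals2 <- toy_values(7, seed = 2)
  colnames(vals2) <- default_schema()$name
  vals2[, "Itp"] <- c(5, 6, 7, 8, 12, 99, 99)
  col2 <- toy_column(vals2, rib_end = 2, chevron_start = 6, status = status2)
  out2 <- apply_absence_rules(label_segments(col2))
  expect_equal(unname(out2$values[6:7, "Itp"]), c(12, 12))
  expect_equal(unname(out2$values[6:7, "Wtp"]), c(0, 0))

  # lumbar metapophysis exception: mean of flanking Hm, not zero
  status3 <- matrix("measured", 7, 16,
                    dimnames = list(NULL, default_schema()$name))
  status3[4, c("Hm", "Wm")] <- "absent"
  vals3 <- toy_values(7, seed = 3)
  colnames(vals3) <- default_schema()$name
  vals3[, "Hm"] <- c(1, 2, 4, 99, 6, 7, 8)
  col3 <- toy_column(vals3, rib_end = 2, chevron_start = 6, status = status3)
  out3 <- apply_absence_rules(label_segments(col3))
  expect_equal(unname(out3$values[4, "Hm"]), 5)  # position 4 is lumbar (ribs to 2)
  expect_equal(unname(out3$values[4, "Wm"]), 0)  # other metapophysis linears zeroed

  # all-absent angular measurement is an error
  status4 <- matrix("measured", 7, 16,
                    dimnames = list(NULL, default_schema()$name))
  status4[, "Inp"] <- "absent"
  col4 <- toy_column(toy_values(7), rib_end = 2, chevron_start = 6,
                     status = status4)
  expect_error(apply_absence_rules(label_segments(col4)), "every vertebra")
})

test_that("broken measurements are interpolated from nearest neighbours", {
  vals <- toy_values(6)
  colnames(vals) <- default_schema()$name
  vals[, "Wc"] <- c(8, 9, 10, 99, 14, 15)
  vals[, "Hc"] <- c(99, 9, 10, 11, 12, 13)
  vals[, "Lc"] <- c(10, 99, 99, 16, 17, 18)
  status <- matrix("measured", 6, 16,
                   dimnames = list(NULL, default_schema()$name))
  status[4, "Wc"] <- "broken"
  status[1, "Hc"] <- "broken"
  status[2:3, "Lc"] <- "broken"
  col <- toy_column(vals, rib_end = 2, chevron_start = 5, status = status)
  out <- impute_broken(apply_absence_rules(label_segments(col)))
  expect_equal(unname(out$values[4, "Wc"]), 12)        # mean of 10 and 14
  expect_equal(unname(out$values[1, "Hc"]), 9)         # terminal copy
  expect_equal(unname(out$values[2:3, "Lc"]), c(13, 13))  # both flanked by 10 and 16

  status[, "Wc"] <- "broken"
  col_bad <- toy_column(vals, rib_end = 2, chevron_start = 5, status = status)
  expect_error(impute_broken(label_segments(col_bad)), "every vertebra")
})

test_that("cleaning is idempotent and never touches measured values", {
  sim <- simulate_column(column_blueprint(
    n = 36, r = 4, seed = 5,
    absence = data.frame(measurement = c("Inp", "Hm", "Itp"),
                         start = c(30, 18, 34), end = c(36, 19, 36))),
    seed = 3)
  col <- sim$column
  raw <- col$values
  once <- impute_broken(apply_absence_rules(label_segments(col)))
  twice <- impute_broken(apply_absence_rules(once))
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  measured <- once$status == "measured"
  expect_equal(once$values[measured], raw[measured])
})

test_that("z-scoring gives unit-SD variables and is idempotent", {
  vals <- toy_values(5)
  vals[, 1] <- c(1, 2, 3, 4, 5)
  col <- toy_column(vals, chevron_start = 4)
  z <- zscore_column(col)
  expect_equal(unname(z$values[, 1]), (1:5 - 3) / sd(1:5), tolerance = 1e-12)
  expect_true(all(abs(colMeans(z$values)) < 1e-12))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-12))
  z2 <- zscore_column(z)
  expect_equal(z2$values, z$values, tolerance = 1e-10)

  vals[, 2] <- 5
  expect_warning(zc <- zscore_column(toy_column(vals, chevron_start = 4)),
                 "constant")
  expect_true(all(zc$values[, 2] == 0))

  expect_error(zscore_column(toy_column(toy_values(1), chevron_start = 2)),
               "at least 2")
})

test_that("three-value variable z-scores to the textbook pattern", {
  vals <- toy_values(3)
  vals[, 1] <- c(1, 2, 3)
  z <- zscore_column(toy_column(vals, rib_end = 1, chevron_start = 3))
  expect_equal(unname(z$values[, 1]), c(-1, 0, 1))
})

test_that("segment labelling follows ribs, chevrons and fluke flags", {
  col <- toy_column(toy_values(40), rib_end = 10, chevron_start = 25,
                    fluke_n = 3)
  lab <- label_segments(col)
  expect_equal(lab$segments[1:10], rep("thoracic", 10))
  expect_equal(lab$segments[11:24], rep("lumbar", 14))
  expect_equal(lab$segments[25:37], rep("caudal", 13))
  expect_equal(lab$segments[38:40], rep("fluke", 3))
  expect_equal(lab$precaudal_boundary, 24)
  expect_equal(unname(table(segment_side(lab))[c("precaudal", "caudal")]),
               c(24, 16), ignore_attr = TRUE)

  # no fluke flags, chevrons to the end
  col2 <- toy_column(toy_values(30), rib_end = 10, chevron_start = 20)
  lab2 <- label_segments(col2)
  expect_equal(sum(lab2$segments == "caudal"), 11)

  # chevron anterior to ribs is anatomically impossible
  vals <- toy_values(12)
  flags <- data.frame(rib_bearing = c(rep(TRUE, 10), FALSE, FALSE),
                      rib_head = c(rep("single", 10), "none", "none"),
                      chevron_bearing = c(FALSE, FALSE, TRUE, rep(FALSE, 7),
                                          TRUE, TRUE),
                      fluke = FALSE)
  bad <- specimen_column("spA", "spA_1", vals, flags)
  expect_error(label_segments(bad), "anterior")
})

test_that("species grouping retains the highest vertebral count", {
  c1 <- toy_column(toy_values(10), chevron_start = 8, specimen = "a")
  c2 <- toy_column(toy_values(14), chevron_start = 10, specimen = "b")
  c3 <- toy_column(toy_values(12), chevron_start = 9, specimen = "c",
                   species = "spB")
  g <- species_groups(list(c1, c2, c3))
  expect_named(g, c("spA", "spB"))
  expect_equal(g$spA$retained_count, 14)
  expect_length(g$spA$columns, 2)
})

test_that("the default schema has 14 linear and 2 angular measurements", {
  sch <- default_schema()
  expect_equal(sum(sch$kind == "linear"), 14)
  expect_equal(sch$name[sch$kind == "angular"], c("Inp", "Itp"))
  expect_true(all(c("Hc", "Wc", "Hm") %in% sch$name[sch$kind == "linear"]))
  expect_error(measurement_schema(c("a", "a"), c("linear", "linear"),
                                  c("x", "x")), "unique")
})
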