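# Per-image aggregation, normalization and the statistics toolkit.

fakeRecords <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    plate_id = "p",
    well = sample(c("A1", "A2", "B1"), n, TRUE),
    field = sample(0:3, n, TRUE),
    cell = seq_len(n),
    cell_line = "x", treatment = "basal",
    live = runif(n) < 0.85,
    nucleus_area_px = 100L, cell_area_px = 900L,
    mean_intensity_cell = rlnorm(n, 6, 0.4),
    mean_intensity_mito = rlnorm(n, 7, 0.4),
    n_mito = rpois(n, 5),
    mean_mito_area_px = rlnorm(n, 3, 0.3),
    total_mito_area_fraction = runif(n, 0, 0.5),
    aspect_ratio = runif(n, 0.2, 1),
    major_axis_len_px = rlnorm(n, 2, 0.3)))
}

test_that("per-image aggregation is the unweighted mean over live cells", {
  rec <- data.frame(plate_id = "p", well = "A1", field = 0L, cell = 1:4,
                    cell_line = "x", treatment = "basal",
                    live = c(TRUE, TRUE, TRUE, FALSE),
                    nucleus_area_px = 1L, cell_area_px = 2L,
                    mean_intensity_cell = c(10, 20, 30, 1000),
                    mean_intensity_mito = c(1, 2, 3, 4),
                    n_mito = 1L, mean_mito_area_px = 1,
                    total_mito_area_fraction = 0.1, aspect_ratio = 0.5,
                    major_axis_len_px = 3)
  s <- aggregatePerImage(rec, minCells = 1L)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_intensity_cell, 20)  # dead cell excluded
  expect_equal(s$n_cells_live, 3)
  expect_equal(s$pct_dead, 25)
})

test_that("fields below the live-cell minimum are dropped", {
  rec <- fakeRecords(40)
  rec$live <- FALSE
  expect_message(s <- aggregatePerImage(rec, minCells = 5L), "dropped")
  expect_equal(nrow(s), 0)
})

test_that("aggregation equals a brute-force group-by on 1000 records", {
  rec <- fakeRecords(1000, seed = 5)
  s <- aggregatePerImage(rec, minCells = 1L)
  for (i in seq_len(nrow(s))) {
    sub <- rec[rec$well == s$well[i] & rec$field == s$field[i] & rec$live, ]
    expect_equal(s$mean_intensity_cell[i], mean(sub$mean_intensity_cell))
    expect_equal(s$aspect_ratio[i], mean(sub$aspect_ratio))
    expect_equal(s$n_cells_live[i], nrow(sub))
  }
})

test_that("normalization divides by the control-basal center", {
  s <- data.frame(plate_id = "p", well = c("A1", "A1", "A1", "B1"),
                  field = 0:3, cell_line = "x", treatment = "basal",
                  n_cells_live = 10, pct_dead = 0,
                  mean_intensity_cell = c(0.8, 1.0, 1.2, 0.7))
  layout <- parsePlateLayout(writeLayoutFixture(withr::local_tempfile(
    fileext = ".yaml")))
  n <- normalizeToControl(s, layout, center = "median",
                          readouts = "mean_intensity_cell")
  expect_equal(n$mean_intensity_cell[4], 0.7)   # divided by median 1.0
  expect_equal(median(n$mean_intensity_cell[n$control_basal]), 1)
  # idempotence
  n2 <- normalizeToControl(n, layout, center = "median",
                           readouts = "mean_intensity_cell")
  expect_equal(n2$mean_intensity_cell, n$mean_intensity_cell)
})

test_that("normalization errors are explicit", {
  s <- data.frame(plate_id = "p", well = "B1", field = 0,
                  mean_intensity_cell = 1)
  layout <- parsePlateLayout(writeLayoutFixture(withr::local_tempfile(
    fileext = ".yaml")))
  s$control_basal <- FALSE
  expect_error(normalizeToControl(s, layout), "control-basal")
  s2 <- data.frame(plate_id = "p", well = c("A1", "B1"), field = 0:1,
                   control_basal = c(TRUE, FALSE),
                   mean_intensity_cell = c(0, 2))
  expect_error(normalizeToControl(s2, readouts = "mean_intensity_cell"),
               "mean_intensity_cell")
})

test_that("Kruskal-Wallis H matches the hand-rank computation", {
  kw <- kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(round(kw$statistic, 3), 3.857)
  for (seed in 1:4) {
    x <- withr::with_seed(seed, round(rnorm(30), 1))  # some ties
    g <- rep(c("a", "b", "c"), 10)
    expect_equal(kruskalWallis(x, g)$statistic, oracleKwH(x, g),
                 tolerance = 1e-12)
  }
})

test_that("identical values across groups give H = 0, p = 1", {
  kw <- kruskalWallis(rep(5, 8), rep(c("a", "b"), 4))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  x <- withr::with_seed(2, rlnorm(40))
  g <- rep(c("a", "b"), 20)
  h1 <- kruskalWallis(x, g)$statistic
  expect_equal(kruskalWallis(log(x), g)$statistic, h1)
  expect_equal(kruskalWallis(x^3, g)$statistic, h1)
})

test_that("Dunn post-hoc comparisons are well-formed and directional", {
  set.seed(11)
  x <- c(rnorm(15), rnorm(15, 3), rnorm(15, 3.1))
  g <- rep(c("lo", "hi1", "hi2"), each = 15)
  kw <- kruskalWallis(x, g)
  ph <- kw$posthoc
  expect_equal(nrow(ph), 3)
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  expect_true(all(ph$p_adj >= ph$p))
  loHi <- ph[ph$group1 == "hi1" & ph$group2 == "lo", ]
  expect_lt(loHi$p_adj, 0.01)
  same <- ph[ph$group1 == "hi1" & ph$group2 == "hi2", ]
  expect_gt(same$p, 0.1)
})

test_that("KS D matches explicit ECDF enumeration", {
  expect_equal(ksTwoSample(1:4, 1:4)$statistic, 0)
  expect_equal(ksTwoSample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  expect_equal(ksTwoSample(1:4, 2:5)$statistic, 0.25)
  for (seed in 1:4) {
    a <- withr::with_seed(seed, rnorm(17))
    b <- withr::with_seed(seed + 50, rnorm(12, 0.5))
    expect_equal(ksTwoSample(a, b)$statistic, oracleKsD(a, b),
                 tolerance = 1e-12)
  }
})

test_that("coefficient of variation follows the sample-sd formula", {
  expect_equal(coefficientOfVariation(rep(4, 10)), 0)
  expect_equal(coefficientOfVariation(c(2, 4)), sqrt(2) / 3)
  expect_error(coefficientOfVariation(c(-1, 1)), "mean")
})

test_that("well-level CoV averages per well first", {
  vals <- c(1, 3, 10, 30)
  wells <- c("A1", "A1", "B1", "B1")
  expect_equal(coefficientOfVariation(vals, "well", wells),
               sd(c(2, 20)) / mean(c(2, 20)))
})

test_that("cell-level CoV exceeds well-level CoV when cell noise dominates", {
  set.seed(31)
  wellMeans <- rnorm(12, 100, 1)          # tiny well-to-well spread
  cellVals <- unlist(lapply(wellMeans, function(m) rnorm(200, m, 30)))
  wells <- rep(sprintf("W%02d", 1:12), each = 200)
  expect_gt(coefficientOfVariation(cellVals, "cell"),
            coefficientOfVariation(cellVals, "well", wells))
})

test_that("frequency distributions count, normalize and accumulate", {
  fd <- frequencyDistribution(c(1, 1, 2), c(0.5, 1.5, 2.5))
  expect_equal(fd$relative, c(2 / 3, 1 / 3))
  expect_equal(fd$cumulative, c(2 / 3, 1))
  one <- frequencyDistribution(c(5, 5.2), c(0, 10))
  expect_equal(one$relative, 1)
  expect_error(frequencyDistribution(numeric(0), c(0, 1)), "values")
  expect_error(frequencyDistribution(1, c(1, 0)), "increasing")
})

test_that("histogramming matches brute-force counting on 10,000 values", {
  vals <- withr::with_seed(8, rnorm(10000))
  edges <- seq(-3, 3, by = 0.5)
  fd <- frequencyDistribution(vals, edges)
  ref <- oracleHist(vals, edges)
  expect_equal(fd$count, ref)
  expect_equal(sum(fd$relative), 1)
  expect_true(all(diff(fd$cumulative) >= 0))
  expect_equal(fd$cumulative[length(fd$cumulative)], 1)
})

test_that("the ANOVA and t-test utilities detect a plain mean shift", {
  set.seed(13)
  a <- rnorm(30); b <- rnorm(30, 2)
  expect_lt(oneWayAnova(c(a, b), rep(c("a", "b"), each = 30))$p.value, 1e-6)
  expect_lt(tTestGroups(a, b)$p.value, 1e-6)
  expect_gt(oneWayAnova(c(a, a), rep(c("a", "b"), each = 30))$p.value, 0.9)
})

test_that("statsReport produces a tidy table over readouts", {
  rec <- fakeRecords(600, seed = 9)
  rec$cell_line <- ifelse(rec$well == "B1", "Patient1", "Control1")
  rec$mean_intensity_cell[rec$cell_line == "Patient1"] <-
    rec$mean_intensity_cell[rec$cell_line == "Patient1"] * 0.5
  s <- aggregatePerImage(rec, minCells = 1L)
  s$control_basal <- s$well == "A1"
  n <- normalizeToControl(s)
  rep <- statsReport(n, groupBy = "cell_line")
  expect_true(all(c("readout", "test", "statistic", "p") %in% names(rep)))
  kwRow <- rep[rep$readout == "mean_intensity_cell" &
                 rep$test == "kruskal-wallis", ]
  expect_lt(kwRow$p, 0.01)
})
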