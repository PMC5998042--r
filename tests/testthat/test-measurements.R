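# Per-cell intensity, morphology, viability and marker readouts.

# One live cell occupying a small frame, with two mitochondrial pixels.
intensityScene <- function() {
  nuc <- matrix(0L, 8, 8); soma <- matrix(0L, 8, 8)
  nuc[4, 4] <- 1L
  soma[4:5, 4:5] <- 1L                       # 4-pixel soma
  cells <- new("CellLabels", nuclei = nuc, soma = soma,
               liveIds = 1L, deadIds = integer(0))
  merged <- matrix(0L, 8, 8)
  merged[4, 4:5] <- 1L                       # 2 mito pixels
  mito <- new("MitoLabels", objects = merged, merged = merged,
              parent = c("1" = 1L), mergedParent = c("1" = 1L))
  img <- matrix(0, 8, 8)
  img[4, 4] <- 100; img[4, 5] <- 120; img[5, 4] <- 10; img[5, 5] <- 10
  list(cells = cells, mito = mito, img = img)
}

test_that("intensity means are plain arithmetic over the pixel sets", {
  sc <- intensityScene()
  got <- measureIntensity(sc$img, sc$cells, sc$mito)
  expect_equal(got$mean_intensity_cell, (100 + 120 + 10 + 10) / 4)
  expect_equal(got$mean_intensity_mito, (100 + 120) / 2)
})

test_that("a cell with no mitochondrial pixels gets a missing mito mean", {
  sc <- intensityScene()
  empty <- new("MitoLabels", objects = matrix(0L, 8, 8),
               merged = matrix(0L, 8, 8),
               parent = setNames(integer(0), character(0)),
               mergedParent = setNames(integer(0), character(0)))
  got <- measureIntensity(sc$img, sc$cells, empty)
  expect_true(is.na(got$mean_intensity_mito))
  expect_false(is.na(got$mean_intensity_cell))
})

test_that("intensity means match a brute-force pixel loop", {
  for (seed in 1:3) {
    img <- randomCountImage(20, 20, 80, seed = seed)
    out <- generateField(tinySpec(imageShape = c(128L, 128L), nCells = 4L,
                                  seed = seed))
    res <- processField(out$field)
    mimg <- channel(out$field, "mito")
    ref <- oracleLabelMeans(mimg, somaLabels(res$cells))
    got <- measureIntensity(mimg, res$cells, res$mito)
    expect_equal(got$mean_intensity_cell,
                 unname(ref[as.character(got$cell)]))
  }
})

test_that("intensity is measured on the original, not enhanced, channel", {
  out <- generateField(tinySpec(nCells = 3L, seed = 31L))
  res <- processField(out$field)
  raw <- channel(out$field, "mito")
  enh <- enhanceTophat(raw, 3L)
  gotRaw <- measureIntensity(raw, res$cells, res$mito)
  gotEnh <- measureIntensity(enh, res$cells, res$mito)
  live <- gotRaw$cell %in% liveIds(res$cells)
  # enhancement strictly lowers soma means (background is subtracted)
  expect_true(all(gotEnh$mean_intensity_cell[live] <
                    gotRaw$mean_intensity_cell[live]))
  expect_equal(measureCells(out$field, res$cells, res$mito)$
                 mean_intensity_cell, gotRaw$mean_intensity_cell)
})

test_that("a shape mismatch between image and labels is an error", {
  sc <- intensityScene()
  expect_error(measureIntensity(matrix(0, 4, 4), sc$cells, sc$mito),
               "shape")
})

test_that("moment ellipses match the explicit second-moment oracle", {
  shapes <- list(
    bar = cbind(rep(5, 9), 3:11),                # 1x9 horizontal bar
    square = as.matrix(expand.grid(4:9, 4:9)),
    lshape = rbind(cbind(2:8, 3), cbind(8, 4:7)))
  for (nm in names(shapes)) {
    px <- shapes[[nm]]
    lab <- matrix(0L, 14, 14)
    lab[px] <- 1L
    got <- mitoHCS:::ellipseByLabel(lab, 1L)
    ref <- oracleEllipse(px)
    expect_equal(got$major, ref$major, tolerance = 1e-12)
    expect_equal(got$minor, ref$minor, tolerance = 1e-12)
    expect_equal(got$aspect, ref$aspect, tolerance = 1e-12)
  }
})

test_that("a thin bar is elongated and a disc is round", {
  lab <- matrix(0L, 16, 16)
  lab[8, 4:12] <- 1L
  bar <- mitoHCS:::ellipseByLabel(lab, 1L)
  expect_lt(bar$aspect, 0.2)
  expect_gt(bar$aspect, 0)           # unit-square pixels: never exactly 0
  disc <- matrix(0L, 32, 32)
  for (i in -9:9) for (j in -9:9)
    if (i^2 + j^2 <= 81) disc[16 + i, 16 + j] <- 1L
  d <- mitoHCS:::ellipseByLabel(disc, 1L)
  expect_gt(d$aspect, 0.95)
  expect_lt(abs(d$major - 19), 1.5)  # ~ the disc diameter (rasterized)
})

test_that("single pixels have aspect ratio exactly 1", {
  lab <- matrix(0L, 5, 5); lab[3, 3] <- 1L
  expect_equal(mitoHCS:::ellipseByLabel(lab, 1L)$aspect, 1)
})

test_that("moment axes agree with EBImage on a thick object", {
  lab <- matrix(0L, 40, 40)
  lab[10:30, 15:24] <- 1L  # 21x10 rectangle: 1/12 correction negligible
  got <- mitoHCS:::ellipseByLabel(lab, 1L)
  fm <- EBImage::computeFeatures.moment(lab)
  expect_equal(got$major, unname(fm[1, "m.majoraxis"]), tolerance = 0.01)
})

test_that("total mitochondrial area fraction is total mito over cell area", {
  nuc <- matrix(0L, 40, 40); soma <- matrix(0L, 40, 40)
  nuc[18:22, 18:22] <- 1L
  soma[4:35, 4:35] <- 1L   # area 1024
  cells <- makeCellLabels(nuc, soma)
  merged <- matrix(0L, 40, 40)
  merged[6:15, 6:15] <- 1L  # 100 px
  merged[25:29, 25:34] <- 2L  # 50 px
  mito <- new("MitoLabels", objects = merged, merged = merged,
              parent = c("1" = 1L, "2" = 1L),
              mergedParent = c("1" = 1L, "2" = 1L))
  got <- measureMorphology(mito, cells)
  expect_equal(got$total_mito_area_fraction, 150 / 1024)
  expect_equal(got$n_mito, 2L)
  expect_equal(got$mean_mito_area_px, 75)
})

test_that("morphology fields are missing exactly when n_mito is zero", {
  out <- generateField(tinySpec(imageShape = c(256L, 256L), nCells = 10L,
                                deadFraction = 0.4, seed = 23L))
  res <- processField(out$field)
  r <- res$records
  zero <- r$n_mito == 0
  for (cl in c("mean_mito_area_px", "total_mito_area_fraction",
               "aspect_ratio", "major_axis_len_px")) {
    expect_true(all(is.na(r[[cl]][zero])))
    expect_true(all(!is.na(r[[cl]][!zero])))
  }
  expect_true(all(r$total_mito_area_fraction[!zero] >= 0 &
                    r$total_mito_area_fraction[!zero] <= 1))
  expect_true(all(r$aspect_ratio[!zero] > 0 & r$aspect_ratio[!zero] <= 1))
})

test_that("mito pixels are conserved between label map and records", {
  out <- generateField(tinySpec(imageShape = c(256L, 256L), nCells = 8L,
                                seed = 29L))
  res <- processField(out$field)
  r <- res$records
  totalFromRecords <- sum(r$total_mito_area_fraction * r$cell_area_px,
                          na.rm = TRUE)
  expect_equal(round(totalFromRecords), sum(res$mito@merged > 0))
})

test_that("mito means exceed whole-cell means when mitochondria are the
           only supra-background structure in the soma", {
  spec <- tinySpec(imageShape = c(256L, 256L), nCells = 8L,
                   mitoCytoFraction = 0, seed = 37L)
  res <- processField(generateField(spec)$field)
  r <- res$records
  has <- r$n_mito > 0
  expect_true(all(r$mean_intensity_mito[has] > r$mean_intensity_cell[has]))
})

test_that("viability counts follow their definition", {
  nuc <- matrix(0L, 4, 4); soma <- matrix(0L, 4, 4)
  cells <- new("CellLabels", nuclei = nuc, soma = soma,
               liveIds = integer(0), deadIds = integer(0))
  expect_true(is.na(measureViability(cells)$pctDead))
  nuc2 <- matrix(1:10, nrow = 1)
  cells2 <- new("CellLabels", nuclei = nuc2, soma = nuc2,
                liveIds = 1:8, deadIds = 9:10)
  v <- measureViability(cells2)
  expect_equal(v$nLive, 8)
  expect_equal(v$pctDead, 20)
})

test_that("marker positivity hits the boundary cases", {
  out <- generateField(tinySpec(imageShape = c(192L, 192L), nCells = 6L,
                                seed = 41L))
  nucCh <- channel(out$field, "nuclear")
  cytCh <- channel(out$field, "cytoplasm")
  expect_equal(markerPositivity(nucCh, cytCh), 100)
  blank <- matrix(100, 192, 192)
  expect_equal(markerPositivity(nucCh, blank), 0)
})

test_that("simulated marker fractions are recovered", {
  # non-overlapping cells: a marker-negative nucleus inside a positive
  # neighbor's soma footprint would capture foreground and read positive
  spec <- tinySpec(imageShape = c(512L, 512L), nCells = 50L,
                   deadFraction = 0, markerFraction = 0.57,
                   minSeparationPx = 40, seed = 47L)
  pct <- truthPct <- numeric(3)
  for (i in 1:3) {
    spec@seed <- 500L + i
    out <- generateField(spec)
    pct[i] <- markerPositivity(channel(out$field, "nuclear"),
                               channel(out$field, "marker"))
    truthPct[i] <- 100 * mean(truthCells(out$truth)$markerPositive)
  }
  # ground-truth recovery per field; the realized truth fraction itself
  # scatters around the simulated 57% with binomial noise
  expect_true(all(abs(pct - truthPct) < 5))
  expect_lt(abs(mean(truthPct) - 57), 3 * sqrt(57 * 43 / 150))
})
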