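# Nucleus segmentation, propagation and viability classification.

test_that("Otsu threshold matches the exhaustive-search oracle", {
  for (seed in 1:5) {
    img <- withr::with_seed(seed, {
      m <- matrix(rpois(24 * 24, 15), 24, 24)
      m[8:16, 8:16] <- m[8:16, 8:16] + rpois(81, 180)
      m
    })
    expect_identical(mitoHCS:::otsuThreshold(img), oracleOtsu(img))
  }
})

test_that("Otsu threshold agrees with EBImage's within one count", {
  img <- withr::with_seed(9, {
    m <- matrix(rpois(64 * 64, 30), 64, 64)
    m[20:40, 20:40] <- m[20:40, 20:40] + 400
    m
  })
  ours <- mitoHCS:::otsuThreshold(img)
  ebi <- EBImage::otsu(img / 65535, range = c(0, 1), levels = 65536) * 65535
  expect_lt(abs(ours - ebi), 1.5)
})

test_that("two bright discs give two nucleus labels (oracle-checked)", {
  img <- matrix(10, 40, 40)
  for (p in list(c(10, 10), c(30, 30)))
    for (i in -4:4) for (j in -4:4)
      if (i^2 + j^2 <= 16) img[p[1] + i, p[2] + j] <- 200
  params <- segmentationParams(nucleusMinAreaPx = 10L, declump = "none")
  lab <- segmentNuclei(img, params)
  expect_equal(max(lab), 2)
  thr <- oracleOtsu(img)
  expect_identical(lab, oracleLabel8(img > thr))
})

test_that("degenerate nuclear inputs give empty label maps", {
  expect_warning(lab <- segmentNuclei(matrix(7, 16, 16)), "constant")
  expect_equal(max(lab), 0)
  # a 20-px disc dies to a 50-px minimum-area filter
  img <- matrix(0, 30, 30)
  img[13:17, 13:16] <- 500
  lab <- segmentNuclei(img, segmentationParams(nucleusMinAreaPx = 50L,
                                               declump = "none"))
  expect_equal(max(lab), 0)
})

test_that("8-connected labeling matches the flood-fill oracle", {
  for (seed in 1:6) {
    mask <- withr::with_seed(seed, matrix(runif(30 * 30) < 0.35, 30, 30))
    expect_identical(mitoHCS:::labelComponents(mask), oracleLabel8(mask))
  }
})

test_that("propagation matches brute-force minimum-cost search", {
  for (seed in 1:4) {
    nr <- 24; nc <- 24
    img <- withr::with_seed(seed, matrix(rpois(nr * nc, 100), nr, nc))
    seeds <- matrix(0L, nr, nc)
    seeds[6:8, 6:8] <- 1L
    seeds[16:18, 14:16] <- 2L
    mask <- matrix(TRUE, nr, nc)
    mask[1:4, 12] <- FALSE  # a notch to force non-trivial geodesics
    got <- propagateLabels(img, seeds, mask, lambda = 0.05)
    ref <- oraclePropagate(img, seeds, mask, lambda = 0.05)
    expect_identical(got, ref$labels)
  }
})

test_that("two nuclei in one merged bright region split it completely", {
  img <- matrix(5, 30, 40)
  img[10:20, 8:32] <- 300  # one merged bright region spanning both seeds
  seeds <- matrix(0L, 30, 40)
  seeds[14:16, 10:12] <- 1L
  seeds[14:16, 28:30] <- 2L
  lab <- propagateLabels(img, seeds, img > 100, lambda = 0.05)
  expect_true(all(lab[img > 100] > 0))   # every foreground pixel assigned
  expect_setequal(unique(as.integer(lab[lab > 0])), c(1L, 2L))
  ref <- oraclePropagate(img, seeds, img > 100, lambda = 0.05)
  expect_identical(lab, ref$labels)
  # left half of the plateau belongs to seed 1, right half to seed 2
  expect_equal(lab[15, 10], 1L)
  expect_equal(lab[15, 30], 2L)
})

test_that("an all-background cytoplasm channel collapses soma onto nuclei", {
  out <- generateField(tinySpec(nCells = 3L, seed = 6L))
  nuc <- segmentNuclei(channel(out$field, "nuclear"))
  flat <- matrix(100, 128, 128)
  soma <- segmentSoma(flat, nuc)
  expect_identical(soma, nuc)
})

test_that("soma labels equal nucleus labels and contain their nuclei", {
  out <- generateField(tinySpec(imageShape = c(256L, 256L), nCells = 10L,
                                deadFraction = 0.3, seed = 13L))
  cells <- segmentCells(out$field)
  nuc <- nucleiLabels(cells)
  soma <- somaLabels(cells)
  expect_setequal(unique(as.integer(soma[soma > 0])),
                  unique(as.integer(nuc[nuc > 0])))
  expect_true(all(soma[nuc > 0] == nuc[nuc > 0]))
  # partition is exhaustive and exclusive
  expect_length(intersect(liveIds(cells), deadIds(cells)), 0)
  expect_setequal(c(liveIds(cells), deadIds(cells)),
                  unique(as.integer(nuc[nuc > 0])))
})

test_that("segmentation is invariant to a constant intensity offset", {
  out <- generateField(tinySpec(imageShape = c(192L, 192L), nCells = 6L,
                                deadFraction = 0.2, seed = 17L))
  fld <- out$field
  shifted <- FieldImage(lapply(fld@channels, function(m) m + 500),
                        plateId = fld@plateId, well = fld@well,
                        fieldIndex = fld@fieldIndex)
  a <- segmentCells(fld)
  b <- segmentCells(shifted)
  expect_identical(nucleiLabels(a), nucleiLabels(b))
  expect_identical(somaLabels(a), somaLabels(b))
  expect_identical(liveIds(a), liveIds(b))
})

test_that("viability follows the soma-vs-nucleus area rule", {
  nuc <- matrix(0L, 30, 30)
  soma <- matrix(0L, 30, 30)
  nuc[2:11, 2:16] <- 1L           # nucleus area 150
  soma[2:21, 2:21] <- 1L          # soma area 400 -> live
  nuc[25:27, 2:11] <- 2L          # nucleus area 30
  soma[25:27, 2:11] <- 2L         # soma area == nucleus area -> dead
  cls <- classifyViability(nuc, soma)
  expect_equal(cls$liveIds, 1L)
  expect_equal(cls$deadIds, 2L)
})

test_that("a soma label without a nucleus is an internal error", {
  nuc <- matrix(0L, 10, 10); soma <- matrix(0L, 10, 10)
  soma[2:4, 2:4] <- 3L
  expect_error(classifyViability(nuc, soma), "consistency")
})

test_that("classified dead fraction recovers the simulated one", {
  # 500 cells across ten fields at dead fraction 0.2
  spec <- tinySpec(imageShape = c(512L, 512L), nCells = 50L,
                   deadFraction = 0.2)
  total <- dead <- truthDead <- truthTotal <- 0
  for (i in 1:10) {
    spec@seed <- 400L + i
    out <- generateField(spec)
    cells <- segmentCells(out$field)
    total <- total + length(liveIds(cells)) + length(deadIds(cells))
    dead <- dead + length(deadIds(cells))
    tc <- truthCells(out$truth)
    truthTotal <- truthTotal + nrow(tc)
    truthDead <- truthDead + sum(!tc$live)
  }
  expect_gte(total, 450)
  expect_lt(abs(dead / total - truthDead / truthTotal), 0.03)
})
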