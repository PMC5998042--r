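# Shared fixture builders: fast low-resolution field specs and hand-made
# label maps used across test files.

# A small, quick-to-render field spec; override freely.
tinySpec <- function(...) {
  args <- list(...)
  defaults <- list(imageShape = c(128L, 128L), nCells = 4L,
                   deadFraction = 0, seed = 1L)
  do.call(syntheticFieldSpec, modifyList(defaults, args))
}

# Deterministic random test image of integer counts.
randomCountImage <- function(nr, nc, lambda = 40, seed = 1) {
  withr::with_seed(seed, matrix(rpois(nr * nc, lambda), nr, nc))
}

# Build a CellLabels object from plain matrices (computes live/dead by
# the area rule, bypassing segmentation).
makeCellLabels <- function(nuclei, soma) {
  cls <- classifyViability(nuclei, soma)
  new("CellLabels", nuclei = nuclei, soma = soma,
      liveIds = cls$liveIds, deadIds = cls$deadIds)
}

# Write a small 4-well layout YAML and return its path.
writeLayoutFixture <- function(path) {
  writeLines(c(
    "plate_id: simplate",
    "wells:",
    "  A1: {cell_line: Control1, treatment: basal, control_basal: true}",
    "  A2: {cell_line: Control1, treatment: CCCP}",
    "  B1: {cell_line: Patient1, treatment: basal}",
    "  B2: {cell_line: Patient1, treatment: CCCP}"), path)
  path
}

# Nucleus-detection matching against ground truth: a detection matches a
# truth cell if its centroid lies inside the truth nucleus disc; greedy
# one-to-one matching by distance.
matchNuclei <- function(nuclei, truth) {
  cent <- mitoHCS:::labelCentroids(nuclei)
  nDet <- nrow(cent); nTru <- nrow(truth)
  if (nDet == 0 || nTru == 0)
    return(list(tp = 0L, nDet = nDet, nTru = nTru))
  d2 <- outer(cent[, 1], truth$row, "-")^2 + outer(cent[, 2], truth$col, "-")^2
  ok <- d2 <= matrix(truth$nucleusRadius^2, nDet, nTru, byrow = TRUE)
  d2[!ok] <- Inf
  tp <- 0L
  while (any(is.finite(d2))) {
    ix <- arrayInd(which.min(d2), dim(d2))
    tp <- tp + 1L
    d2[ix[1], ] <- Inf
    d2[, ix[2]] <- Inf
  }
  list(tp = tp, nDet = nDet, nTru = nTru)
}

# Run the full pipeline over generated fields for one condition and
# return per-cell records annotated with a group label.
simulateGroupRecords <- function(nFields, spec, group, well,
                                 seedBase, treatment = "basal") {
  recs <- vector("list", nFields)
  for (i in seq_len(nFields)) {
    spec@seed <- seedBase + i
    out <- generateField(spec, well = well, fieldIndex = i - 1L)
    res <- processField(out$field)
    res$records$cell_line <- group
    res$records$treatment <- treatment
    recs[[i]] <- res$records
  }
  do.call(rbind, recs)
}
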