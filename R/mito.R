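# Mitochondrial enhancement, segmentation, cell assignment and merging.

#' Parameters for mitochondrial segmentation
#'
#' @slot tophatRadiusPx integer(1) >= 1: radius of the flat disc
#'   structuring element of the white top-hat filter.
#' @slot fixedThreshold numeric(1) > 0: intensity threshold (counts)
#'   applied to the enhanced image.  A fixed, not per-image, threshold
#'   lets membrane-potential differences show up as segmented-area
#'   differences; this value is a mandatory, logged configuration entry.
#' @slot mitoMinAreaPx integer(1) >= 1: minimum object area (pixels).
#' @slot assignMethod character(1): "centroid" (object belongs to the
#'   soma containing its centroid) or "majority" (majority-pixel
#'   overlap).
#' @export
setClass("MitoParams",
  representation(tophatRadiusPx = "integer", fixedThreshold = "numeric",
                 mitoMinAreaPx = "integer", assignMethod = "character"))

setValidity("MitoParams", function(object) {
  if (object@tophatRadiusPx < 1L) return("tophatRadiusPx must be >= 1")
  if (object@fixedThreshold <= 0) return("fixedThreshold must be > 0")
  if (object@mitoMinAreaPx < 1L) return("mitoMinAreaPx must be >= 1")
  if (!object@assignMethod %in% c("centroid", "majority"))
    return("assignMethod must be 'centroid' or 'majority'")
  TRUE
})

#' Construct mitochondrial segmentation parameters
#'
#' @param tophatRadiusPx,fixedThreshold,mitoMinAreaPx,assignMethod see
#'   \linkS4class{MitoParams}.  The default threshold of 120 counts is
#'   calibrated on the synthetic-plate noise model: about five times the
#'   total per-pixel noise sd (shot + read) inside a basal-condition
#'   soma; real plates must set it for their acquisition settings.
#' @return a \linkS4class{MitoParams}.
#' @export
mitoParams <- function(tophatRadiusPx = 3L, fixedThreshold = 120,
                       mitoMinAreaPx = 2L,
                       assignMethod = c("centroid", "majority")) {
  new("MitoParams", tophatRadiusPx = as.integer(tophatRadiusPx),
      fixedThreshold = fixedThreshold,
      mitoMinAreaPx = as.integer(mitoMinAreaPx),
      assignMethod = match.arg(assignMethod))
}

setMethod("show", "MitoParams", function(object) {
  cat(sprintf(
    "MitoParams: top-hat radius %d px, fixed threshold %g, min area %d px, assign %s\n",
    object@tophatRadiusPx, object@fixedThreshold, object@mitoMinAreaPx,
    object@assignMethod))
})

#' White top-hat enhancement of the mitochondrial channel
#'
#' Subtracts the grayscale opening (flat disc structuring element) from
#' the input, suppressing structures wider than the disc -- diffuse and
#' out-of-focus background -- while retaining thin or punctate bright
#' objects.  The output is pointwise >= 0 and <= the input
#' (anti-extensivity of the opening).
#'
#' @param mitoChannel 2-D numeric matrix of counts.
#' @param tophatRadiusPx disc radius in pixels (>= 1).
#' @return enhanced matrix, same shape.
#' @export
enhanceTophat <- function(mitoChannel, tophatRadiusPx = 3L) {
  stopifnot(is.matrix(mitoChannel), tophatRadiusPx >= 1)
  brush <- EBImage::makeBrush(2L * as.integer(tophatRadiusPx) + 1L, "disc")
  opened <- grayDilate(grayErode(mitoChannel, brush), brush)
  out <- mitoChannel - opened
  out[out < 0] <- 0
  out
}

# Flat grayscale erosion/dilation with an arbitrary structuring element,
# as a running min/max over the element's offsets.  Outside-image pixels
# act as +Inf for erosion and -Inf for dilation (border replication of
# the extreme), the usual convention for flat morphology.
grayMorph <- function(img, brush, op) {
  ctr <- (dim(brush) + 1) / 2
  offs <- which(brush > 0, arr.ind = TRUE)
  fill <- if (identical(op, pmin)) Inf else -Inf
  out <- matrix(fill, nrow(img), ncol(img))
  for (i in seq_len(nrow(offs))) {
    dr <- offs[i, 1] - ctr[1]
    dc <- offs[i, 2] - ctr[2]
    out <- op(out, shiftMatrix(img, dr, dc, fill))
  }
  out
}

grayErode <- function(img, brush) grayMorph(img, brush, pmin)

grayDilate <- function(img, brush) {
  # dilation reflects the structuring element; makeBrush discs are
  # symmetric, but reflect anyway for correctness with any element
  grayMorph(img, brush[rev(seq_len(nrow(brush))), rev(seq_len(ncol(brush))),
                       drop = FALSE], pmax)
}

#' Segment mitochondria from the enhanced image with a fixed threshold
#'
#' @param enhanced matrix from \code{\link{enhanceTophat}}.
#' @param fixedThreshold intensity cut (counts, > 0).
#' @param mitoMinAreaPx minimum object area; smaller components dropped.
#' @return integer label matrix (8-connected components, labels 1..M).
#' @export
segmentMitochondria <- function(enhanced, fixedThreshold = 120,
                                mitoMinAreaPx = 2L) {
  stopifnot(fixedThreshold > 0)
  mask <- enhanced > fixedThreshold
  lab <- labelComponents(mask)
  filterSmall(lab, mitoMinAreaPx)
}

#' Assign mitochondria to their parent cells
#'
#' Each mitochondrion is assigned to the soma containing its centroid
#' (or, with \code{assignMethod = "majority"}, the soma covering most of
#' its pixels).  Objects falling on background or in a dead cell are
#' removed; surviving objects are trimmed to their parent soma (a pixel
#' outside the parent cell is no cell's readout) and relabeled 1..M.
#'
#' @param mito integer mitochondrion label matrix.
#' @param cells a \linkS4class{CellLabels}.
#' @param assignMethod "centroid" or "majority".
#' @return list with \code{objects} (filtered, relabeled matrix) and
#'   \code{parent} (named integer: object label -> live cell label).
#' @export
assignToCells <- function(mito, cells, assignMethod = "centroid") {
  stopifnot(identical(dim(mito), dim(cells@soma)))
  k <- max(mito)
  empty <- list(objects = matrix(0L, nrow(mito), ncol(mito)),
                parent = setNames(integer(0), character(0)))
  if (k < 1) return(empty)
  soma <- cells@soma
  if (assignMethod == "centroid") {
    cent <- labelCentroids(mito, k)
    ri <- pmin(pmax(round(cent[, 1]) + 1, 1), nrow(mito))
    ci <- pmin(pmax(round(cent[, 2]) + 1, 1), ncol(mito))
    owner <- soma[cbind(ri, ci)]
  } else {
    idx <- which(mito > 0)
    tab <- table(mito[idx], soma[idx])  # includes background column "0"
    owner <- as.integer(colnames(tab)[max.col(tab, ties.method = "first")])
  }
  keep <- owner %in% cells@liveIds
  if (!any(keep)) return(empty)
  oldIds <- which(keep)
  out <- mito
  out[!(mito %in% oldIds)] <- 0L
  # mitochondrial pixels are per-cell readouts: pixels of a retained
  # object lying outside its parent soma belong to no cell and are
  # trimmed, which also keeps the per-cell mito area <= the cell area
  ownerMap <- integer(k)
  ownerMap[oldIds] <- owner[oldIds]
  fg <- out > 0L
  out[fg][soma[fg] != ownerMap[out[fg]]] <- 0L
  if (!any(out > 0L)) return(empty)
  newOrder <- unique(as.integer(out[out > 0L]))
  out <- relabelSequential(out)
  parent <- setNames(ownerMap[newOrder], seq_along(newOrder))
  list(objects = out, parent = parent)
}

#' Merge touching mitochondria within each cell
#'
#' Objects whose pixel sets touch by 8-connectivity and that belong to
#' the same cell are re-classified as a single object (transitive
#' closure); objects in different cells never merge.  Pixel counts are
#' conserved.
#'
#' @param objects integer mitochondrion label matrix.
#' @param parent named integer vector, object label -> cell label.
#' @return list with \code{merged} (label matrix) and
#'   \code{mergedParent} (named integer: merged label -> cell label).
#' @export
mergeTouching <- function(objects, parent) {
  k <- max(objects)
  if (k < 1)
    return(list(merged = objects, mergedParent = setNames(integer(0),
                                                          character(0))))
  stopifnot(all(as.character(seq_len(k)) %in% names(parent)))
  par <- as.integer(parent[as.character(seq_len(k))])
  nr <- nrow(objects); nc <- ncol(objects)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  pairs <- matrix(integer(0), 0, 2)
  for (o in offs) {
    a <- objects
    b <- shiftMatrix(objects, o[1], o[2], 0L)
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  uf <- seq_len(k)
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (par[i] != par[j]) next        # never merge across cells
      ri <- find(i); rj <- find(j)
      if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  merged <- matrix(0L, nr, nc)
  fg <- objects > 0L
  merged[fg] <- root[objects[fg]]
  merged <- relabelSequential(merged)
  newOfRoot <- merged[fg][!duplicated(merged[fg])]
  rootSeen <- root[objects[fg]][!duplicated(merged[fg])]
  mergedParent <- setNames(par[rootSeen], newOfRoot)
  mergedParent <- mergedParent[order(as.integer(names(mergedParent)))]
  list(merged = merged, mergedParent = mergedParent)
}

#' Segment and organize mitochondria within the cells of a field
#'
#' Chains \code{\link{enhanceTophat}},
#' \code{\link{segmentMitochondria}}, \code{\link{assignToCells}} and
#' \code{\link{mergeTouching}}.
#'
#' @param mitoChannel original (unenhanced) mitochondrial channel.
#' @param cells a \linkS4class{CellLabels}.
#' @param params a \linkS4class{MitoParams}.
#' @return a \linkS4class{MitoLabels}.
#' @export
segmentMitoInCells <- function(mitoChannel, cells, params = mitoParams()) {
  validObject(params)
  enh <- enhanceTophat(mitoChannel, params@tophatRadiusPx)
  lab <- segmentMitochondria(enh, params@fixedThreshold,
                             params@mitoMinAreaPx)
  asg <- assignToCells(lab, cells, params@assignMethod)
  mrg <- mergeTouching(asg$objects, asg$parent)
  new("MitoLabels", objects = asg$objects, merged = mrg$merged,
      parent = asg$parent, mergedParent = mrg$mergedParent)
}
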