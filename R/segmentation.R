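# Nucleus segmentation, soma propagation and live/dead classification.

#' Parameters for nucleus/soma segmentation
#'
#' @slot nucleusMinAreaPx integer(1) >= 1: objects smaller than this are
#'   removed from the nucleus mask.
#' @slot declump character(1): "watershed" (distance-transform watershed
#'   splitting of clumped nuclei) or "none".
#' @slot lambda numeric(1) >= 0: propagation regularization, the weight
#'   of the per-step intensity difference against the spatial step
#'   length (counts^-1).
#' @slot borderPolicy character(1): "keep" or "discard" nuclei touching
#'   the image border.
#' @slot minCalceinIntensity numeric(1): optional minimum mean cytoplasm
#'   intensity (counts) for a cell to be classified live; NA disables
#'   the cut and viability is decided by the area rule alone.
#' @export
setClass("SegmentationParams",
  representation(nucleusMinAreaPx = "integer", declump = "character",
                 lambda = "numeric", borderPolicy = "character",
                 minCalceinIntensity = "numeric"))

setValidity("SegmentationParams", function(object) {
  if (object@nucleusMinAreaPx < 1L) return("nucleusMinAreaPx must be >= 1")
  if (!object@declump %in% c("watershed", "none"))
    return("declump must be 'watershed' or 'none'")
  if (object@lambda < 0) return("lambda must be >= 0")
  if (!object@borderPolicy %in% c("keep", "discard"))
    return("borderPolicy must be 'keep' or 'discard'")
  TRUE
})

#' Construct segmentation parameters
#'
#' @param nucleusMinAreaPx,declump,lambda,borderPolicy,minCalceinIntensity
#'   see \linkS4class{SegmentationParams}.
#' @return a \linkS4class{SegmentationParams}.
#' @export
segmentationParams <- function(nucleusMinAreaPx = 80L,
                               declump = c("watershed", "none"),
                               lambda = 0.05,
                               borderPolicy = c("keep", "discard"),
                               minCalceinIntensity = NA_real_) {
  new("SegmentationParams",
      nucleusMinAreaPx = as.integer(nucleusMinAreaPx),
      declump = match.arg(declump), lambda = lambda,
      borderPolicy = match.arg(borderPolicy),
      minCalceinIntensity = minCalceinIntensity)
}

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf(
    "SegmentationParams: min nucleus area %d px, declump %s, lambda %g, border %s\n",
    object@nucleusMinAreaPx, object@declump, object@lambda,
    object@borderPolicy))
})

#' Segment nuclei from the nuclear-stain channel
#'
#' Otsu threshold on the 65,536-bin histogram of raw counts, hole
#' filling, removal of objects below the minimum area, optional
#' distance-transform watershed declumping, and 8-connected labeling.
#'
#' @param nuclearChannel 2-D numeric matrix of counts.
#' @param params a \linkS4class{SegmentationParams}.
#' @return integer label matrix (0 = background, labels 1..K).
#' @examples
#' out <- generateField(syntheticFieldSpec(imageShape = c(128, 128),
#'                                         nCells = 4, seed = 3))
#' nuc <- segmentNuclei(channel(out$field, "nuclear"), segmentationParams())
#' max(nuc)  # number of nuclei found
#' @export
segmentNuclei <- function(nuclearChannel, params = segmentationParams()) {
  stopifnot(is.matrix(nuclearChannel), length(nuclearChannel) > 0)
  validObject(params)
  thr <- otsuThreshold(nuclearChannel)
  if (is.na(thr)) {
    warning("constant nuclear channel: no nuclei segmented")
    return(matrix(0L, nrow(nuclearChannel), ncol(nuclearChannel)))
  }
  mask <- nuclearChannel > thr
  mask <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask),
                                   ncol(mask))) > 0
  lab <- labelComponents(mask)
  lab <- filterSmall(lab, params@nucleusMinAreaPx)
  if (params@declump == "watershed" && max(lab) > 0) {
    m <- lab > 0
    dm <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
    ext <- max(1L, round(sqrt(params@nucleusMinAreaPx / pi)))
    ws <- EBImage::watershed(dm, tolerance = 1, ext = ext)
    lab <- relabelSequential(matrix(as.integer(ws), nrow(ws), ncol(ws)))
    lab <- filterSmall(lab, params@nucleusMinAreaPx)
  }
  if (params@borderPolicy == "discard" && max(lab) > 0) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0]
    if (length(border)) {
      lab[lab %in% border] <- 0L
      lab <- relabelSequential(lab)
    }
  }
  lab
}

filterSmall <- function(lab, minArea) {
  k <- max(lab)
  if (k < 1) return(lab)
  areas <- labelAreas(lab, k)
  drop <- which(areas < minArea)
  if (length(drop)) {
    lab[lab %in% drop] <- 0L
    lab <- relabelSequential(lab)
  }
  lab
}

#' Seeded propagation of labels over a foreground mask
#'
#' Each foreground pixel is assigned to the seed reachable at minimal
#' accumulated cost, where one step to an 8-neighbor costs the spatial
#' step length (1 or sqrt(2)) plus \code{lambda} times the absolute
#' intensity difference between the two pixels.  Cost ties are broken in
#' favor of the lower seed label.  Implemented as vectorized
#' Bellman-Ford relaxation, so the result is the exact minimum-cost
#' assignment.
#'
#' @param intensity 2-D numeric matrix guiding the propagation.
#' @param seeds integer label matrix of seed regions (cost 0).
#' @param mask logical matrix: pixels eligible for assignment.
#' @param lambda intensity-difference weight (>= 0).
#' @return integer label matrix over \code{mask | seeds}.
#' @export
propagateLabels <- function(intensity, seeds, mask, lambda = 0.05) {
  stopifnot(identical(dim(intensity), dim(seeds)),
            identical(dim(intensity), dim(mask)), lambda >= 0)
  nr <- nrow(intensity); nc <- ncol(intensity)
  lab <- matrix(as.integer(seeds), nr, nc)
  if (max(lab) == 0L) return(matrix(0L, nr, nc))
  mask <- mask | lab > 0
  dist <- matrix(Inf, nr, nc)
  dist[lab > 0] <- 0
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
               c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  step <- c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  # per-offset edge weights are constant across iterations
  w <- vector("list", 8L)
  for (k in 1:8) {
    o <- offs[[k]]
    w[[k]] <- step[k] +
      lambda * abs(intensity - shiftMatrix(intensity, o[1], o[2], Inf))
  }
  eps <- 1e-9
  repeat {
    changed <- FALSE
    for (k in 1:8) {
      o <- offs[[k]]
      cd <- shiftMatrix(dist, o[1], o[2], Inf) + w[[k]]
      cl <- shiftMatrix(lab, o[1], o[2], 0L)
      ok <- mask & is.finite(cd) & cl > 0L
      upd <- ok & (cd < dist - eps |
                     (abs(cd - dist) <= eps & lab > 0L & cl < lab))
      if (any(upd)) {
        dist[upd] <- cd[upd]
        lab[upd] <- cl[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab[!mask] <- 0L
  lab
}

#' Segment cell soma by propagation from nuclei
#'
#' The foreground is the Otsu mask of the cytoplasmic (Calcein) channel
#' united with the nucleus pixels; every foreground pixel is assigned to
#' the nucleus with minimal propagation cost.  Soma labels equal their
#' seed nucleus labels and each soma contains its nucleus, so a cell
#' with no cytoplasmic signal ends up with soma identical to its
#' nucleus.
#'
#' @param cytoplasmChannel 2-D numeric matrix of counts.
#' @param nuclei integer nucleus label matrix (seeds).
#' @param params a \linkS4class{SegmentationParams}.
#' @return integer soma label matrix.
#' @export
segmentSoma <- function(cytoplasmChannel, nuclei,
                        params = segmentationParams()) {
  stopifnot(identical(dim(cytoplasmChannel), dim(nuclei)))
  validObject(params)
  if (max(nuclei) == 0L)
    return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  thr <- otsuThreshold(cytoplasmChannel)
  mask <- if (is.na(thr)) matrix(FALSE, nrow(nuclei), ncol(nuclei)) else
    cytoplasmChannel > thr
  propagateLabels(cytoplasmChannel, nuclei, mask, params@lambda)
}

#' Classify cells live or dead
#'
#' A cell is dead iff its soma area does not exceed its nucleus area
#' (a Calcein-negative cell gains no pixels by propagation, so its soma
#' collapses onto the nucleus).  An optional minimum mean-Calcein
#' intensity cut can additionally mark low-intensity cells dead; it is
#' off by default.
#'
#' @param nuclei,soma integer label matrices sharing the label set.
#' @param cytoplasmChannel optional matrix, needed only when
#'   \code{params@minCalceinIntensity} is set.
#' @param params a \linkS4class{SegmentationParams}.
#' @return list with integer vectors \code{liveIds} and \code{deadIds}.
#' @export
classifyViability <- function(nuclei, soma, cytoplasmChannel = NULL,
                              params = segmentationParams()) {
  nucIds <- sort(unique(as.integer(nuclei[nuclei > 0])))
  somaIds <- sort(unique(as.integer(soma[soma > 0])))
  if (!all(somaIds %in% nucIds))
    stop("internal consistency error: soma label without matching nucleus",
         call. = FALSE)
  if (!length(nucIds))
    return(list(liveIds = integer(0), deadIds = integer(0)))
  k <- max(nucIds)
  nucArea <- labelAreas(nuclei, k)
  somArea <- labelAreas(soma, k)
  dead <- somArea[nucIds] <= nucArea[nucIds]
  if (!is.na(params@minCalceinIntensity)) {
    stopifnot(!is.null(cytoplasmChannel))
    sums <- rowsum(as.numeric(cytoplasmChannel[soma > 0]), soma[soma > 0])
    meanCal <- rep(NA_real_, k)
    meanCal[as.integer(rownames(sums))] <- sums[, 1]
    meanCal <- meanCal / somArea
    dead <- dead | meanCal[nucIds] < params@minCalceinIntensity
  }
  list(liveIds = nucIds[!dead], deadIds = nucIds[dead])
}

#' Segment one field into cells
#'
#' Convenience wrapper chaining \code{\link{segmentNuclei}},
#' \code{\link{segmentSoma}} and \code{\link{classifyViability}}.
#'
#' @param field a \linkS4class{FieldImage} with nuclear and cytoplasm
#'   channels.
#' @param params a \linkS4class{SegmentationParams}.
#' @return a \linkS4class{CellLabels}.
#' @export
segmentCells <- function(field, params = segmentationParams()) {
  nuc <- segmentNuclei(channel(field, "nuclear"), params)
  soma <- segmentSoma(channel(field, "cytoplasm"), nuc, params)
  cls <- classifyViability(nuc, soma, channel(field, "cytoplasm"), params)
  new("CellLabels", nuclei = nuc, soma = soma,
      liveIds = cls$liveIds, deadIds = cls$deadIds)
}
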