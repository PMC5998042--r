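# Per-cell readout panel: intensities (on the ORIGINAL mitochondrial
# channel), moment-ellipse morphology of merged mitochondria, viability
# counts and marker positivity.

# Mean of `img` over the pixels of each label 1..k; NA where a label is
# absent.
meanByLabel <- function(img, lab, k = max(lab)) {
  if (k < 1) return(numeric(0))
  idx <- which(lab > 0)
  out <- rep(NA_real_, k)
  if (!length(idx)) return(out)
  sums <- rowsum(as.numeric(img[idx]), lab[idx])
  n <- tabulate(lab[idx], nbins = k)
  present <- as.integer(rownames(sums))
  out[present] <- sums[, 1] / n[present]
  out
}

#' Per-cell TMRM intensity (whole-cell and mitochondrial)
#'
#' Arithmetic means of the \emph{original} (unenhanced) mitochondrial
#' channel over, per cell, all soma pixels and all mitochondrial pixels.
#' Cells with no mitochondrial pixels get a missing mitochondrial mean.
#'
#' @param mitoChannel original mitochondrial channel matrix.
#' @param cells a \linkS4class{CellLabels}.
#' @param mito a \linkS4class{MitoLabels}.
#' @return data.frame with columns \code{cell},
#'   \code{mean_intensity_cell}, \code{mean_intensity_mito}.
#' @export
measureIntensity <- function(mitoChannel, cells, mito) {
  if (!identical(dim(mitoChannel), dim(cells@soma)))
    stop("shape mismatch between intensity image and label maps",
         call. = FALSE)
  ids <- sort(unique(as.integer(cells@nuclei[cells@nuclei > 0])))
  if (!length(ids))
    return(data.frame(cell = integer(0), mean_intensity_cell = numeric(0),
                      mean_intensity_mito = numeric(0)))
  k <- max(ids)
  cellMean <- meanByLabel(mitoChannel, cells@soma, k)
  # group all mitochondrial pixels of one cell via the merged map
  mitoMean <- rep(NA_real_, k)
  idx <- which(mito@merged > 0)
  if (length(idx)) {
    cellOf <- as.integer(mito@mergedParent[as.character(mito@merged[idx])])
    sums <- rowsum(as.numeric(mitoChannel[idx]), cellOf)
    n <- tabulate(cellOf, nbins = k)
    present <- as.integer(rownames(sums))
    mitoMean[present] <- sums[, 1] / n[present]
  }
  data.frame(cell = ids, mean_intensity_cell = cellMean[ids],
             mean_intensity_mito = mitoMean[ids])
}

# Moment-equivalent ellipse of each label 1..k, treating pixels as unit
# squares (covariance of pixel centers + I/12).  Axis lengths follow the
# 4*sqrt(eigenvalue) convention, so a solid disc of diameter d measures
# approximately d on both axes and a single pixel measures
# 4*sqrt(1/12) on both (aspect ratio exactly 1).
ellipseByLabel <- function(lab, k = max(lab)) {
  out <- data.frame(label = seq_len(k), area = NA_integer_,
                    major = NA_real_, minor = NA_real_,
                    aspect = NA_real_)
  if (k < 1) return(out[0, ])
  idx <- which(lab > 0)
  l <- lab[idx]
  r <- as.numeric((idx - 1L) %% nrow(lab))
  c <- as.numeric((idx - 1L) %/% nrow(lab))
  n <- tabulate(l, nbins = k)
  sr <- rep(0, k); sc <- rep(0, k)
  srr <- rep(0, k); scc <- rep(0, k); src <- rep(0, k)
  agg <- rowsum(cbind(r, c, r * r, c * c, r * c), l)
  present <- as.integer(rownames(agg))
  sr[present] <- agg[, 1]; sc[present] <- agg[, 2]
  srr[present] <- agg[, 3]; scc[present] <- agg[, 4]; src[present] <- agg[, 5]
  mr <- sr / n; mc <- sc / n
  vrr <- srr / n - mr^2 + 1 / 12
  vcc <- scc / n - mc^2 + 1 / 12
  vrc <- src / n - mr * mc
  tr <- vrr + vcc
  det <- sqrt(pmax(0, ((vrr - vcc) / 2)^2 + vrc^2))
  l1 <- tr / 2 + det
  l2 <- pmax(0, tr / 2 - det)
  out$area <- n
  out$major <- 4 * sqrt(l1)
  out$minor <- 4 * sqrt(l2)
  out$aspect <- ifelse(out$major > 0, out$minor / out$major, NA_real_)
  out[n > 0, , drop = FALSE]
}

#' Per-cell mitochondrial morphology panel
#'
#' For each merged mitochondrial object: area (pixel count) and the
#' moment-equivalent ellipse (major-axis length, aspect ratio =
#' minor/major).  Per cell, unweighted means over its objects plus the
#' total mitochondrial area divided by the cell area.  Cells with no
#' mitochondria get missing morphology fields.
#'
#' @param mito a \linkS4class{MitoLabels} (merged map is used).
#' @param cells a \linkS4class{CellLabels}.
#' @return data.frame with columns \code{cell}, \code{n_mito},
#'   \code{mean_mito_area_px}, \code{total_mito_area_fraction},
#'   \code{aspect_ratio}, \code{major_axis_len_px}.
#' @export
measureMorphology <- function(mito, cells) {
  ids <- sort(unique(as.integer(cells@nuclei[cells@nuclei > 0])))
  base <- data.frame(cell = ids, n_mito = integer(length(ids)),
                     mean_mito_area_px = rep(NA_real_, length(ids)),
                     total_mito_area_fraction = rep(NA_real_, length(ids)),
                     aspect_ratio = rep(NA_real_, length(ids)),
                     major_axis_len_px = rep(NA_real_, length(ids)))
  if (!length(ids)) return(base)
  k <- max(mito@merged)
  somaArea <- labelAreas(cells@soma, max(ids))
  # all morphology fields (including the area fraction) are missing
  # exactly when a cell has no mitochondria
  if (k < 1) return(base)
  ell <- ellipseByLabel(mito@merged, k)
  cellOf <- as.integer(mito@mergedParent[as.character(ell$label)])
  agg <- rowsum(cbind(1, ell$area, ell$aspect, ell$major), cellOf)
  present <- as.integer(rownames(agg))
  for (i in seq_along(present)) {
    ci <- match(present[i], base$cell)
    nObj <- agg[i, 1]
    base$n_mito[ci] <- as.integer(nObj)
    base$mean_mito_area_px[ci] <- agg[i, 2] / nObj
    base$aspect_ratio[ci] <- agg[i, 3] / nObj
    base$major_axis_len_px[ci] <- agg[i, 4] / nObj
    base$total_mito_area_fraction[ci] <- agg[i, 2] / somaArea[present[i]]
  }
  base
}

#' Viability counts for one field
#'
#' @param cells a \linkS4class{CellLabels}.
#' @return list with \code{nLive}, \code{nDead} and \code{pctDead}
#'   (percent, NA when the field has no nuclei).
#' @export
measureViability <- function(cells) {
  nLive <- length(cells@liveIds)
  nDead <- length(cells@deadIds)
  list(nLive = nLive, nDead = nDead,
       pctDead = if (nLive + nDead == 0) NA_real_ else
         100 * nDead / (nLive + nDead))
}

#' Percent of nuclei positive for a cytoplasmic marker
#'
#' Nuclei are segmented from the nuclear channel; a soma is propagated
#' for each nucleus on the marker channel; a nucleus is marker-positive
#' iff its propagated soma exceeds the nucleus area (the same rule that
#' separates Calcein-positive live cells from dead ones).  Nuclei with
#' no corresponding cytoplasmic staining are classified negative
#' (non-neuronal when the marker is a neuronal stain).
#'
#' @param nuclearChannel,markerChannel equal-shape matrices.
#' @param params a \linkS4class{SegmentationParams}.
#' @return percent positive in [0, 100], or NA if no nuclei are found.
#' @export
markerPositivity <- function(nuclearChannel, markerChannel,
                             params = segmentationParams()) {
  stopifnot(identical(dim(nuclearChannel), dim(markerChannel)))
  nuc <- segmentNuclei(nuclearChannel, params)
  ids <- sort(unique(as.integer(nuc[nuc > 0])))
  if (!length(ids)) return(NA_real_)
  soma <- segmentSoma(markerChannel, nuc, params)
  cls <- classifyViability(nuc, soma, markerChannel, params)
  100 * length(cls$liveIds) / length(ids)
}

#' Full per-cell readout panel for one field
#'
#' Builds the CellRecord table: provenance, layout annotation, live
#' flag, areas, whole-cell and mitochondrial TMRM intensity, and the
#' four-morphology panel.  Dead cells keep their identity and areas (for
#' viability statistics) but are excluded from mitochondrial readouts by
#' construction (their records carry zero mitochondria).
#'
#' @param field a \linkS4class{FieldImage}.
#' @param cells a \linkS4class{CellLabels}.
#' @param mito a \linkS4class{MitoLabels}.
#' @param layout optional \linkS4class{PlateLayout} for cell_line /
#'   treatment annotation.
#' @return data.frame, one row per cell (see
#'   \code{\link{writeCellTable}} for the column order).
#' @export
measureCells <- function(field, cells, mito, layout = NULL) {
  ids <- sort(unique(as.integer(cells@nuclei[cells@nuclei > 0])))
  k <- if (length(ids)) max(ids) else 0L
  nucArea <- labelAreas(cells@nuclei, k)
  somArea <- labelAreas(cells@soma, k)
  inten <- measureIntensity(channel(field, "mito"), cells, mito)
  morph <- measureMorphology(mito, cells)
  cellLine <- NA_character_
  treatment <- NA_character_
  if (!is.null(layout)) {
    row <- layoutWells(layout)[layoutWells(layout)$well ==
                                 normalizeWell(field@well), ]
    if (nrow(row) == 1L) {
      cellLine <- row$cell_line
      treatment <- row$treatment
    }
  }
  data.frame(
    plate_id = field@plateId, well = normalizeWell(field@well),
    field = field@fieldIndex, cell = ids,
    cell_line = cellLine, treatment = treatment,
    live = ids %in% cells@liveIds,
    nucleus_area_px = nucArea[ids], cell_area_px = somArea[ids],
    mean_intensity_cell = inten$mean_intensity_cell,
    mean_intensity_mito = inten$mean_intensity_mito,
    n_mito = morph$n_mito,
    mean_mito_area_px = morph$mean_mito_area_px,
    total_mito_area_fraction = morph$total_mito_area_fraction,
    aspect_ratio = morph$aspect_ratio,
    major_axis_len_px = morph$major_axis_len_px,
    row.names = NULL)
}

#' Run the full single-field pipeline
#'
#' Segments cells and mitochondria and measures the per-cell panel.
#'
#' @param field a \linkS4class{FieldImage}.
#' @param segParams a \linkS4class{SegmentationParams}.
#' @param mitParams a \linkS4class{MitoParams}.
#' @param layout optional \linkS4class{PlateLayout}.
#' @return list with \code{cells} (\linkS4class{CellLabels}),
#'   \code{mito} (\linkS4class{MitoLabels}) and \code{records}
#'   (data.frame).
#' @export
processField <- function(field, segParams = segmentationParams(),
                         mitParams = mitoParams(), layout = NULL) {
  cells <- segmentCells(field, segParams)
  mito <- segmentMitoInCells(channel(field, "mito"), cells, mitParams)
  records <- measureCells(field, cells, mito, layout)
  list(cells = cells, mito = mito, records = records)
}
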