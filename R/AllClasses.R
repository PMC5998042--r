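#' @import methods
#' @importFrom stats median rnorm rpois runif rlnorm sd setNames
#' @importFrom utils head modifyList packageVersion
NULL

REQUIRED_CHANNELS <- c("nuclear", "cytoplasm", "mito")
KNOWN_CHANNELS <- c("nuclear", "cytoplasm", "mito", "marker")
MAX_COUNT <- 65535

#' FieldImage: one multi-channel imaging field
#'
#' Container for the raw intensity images of a single field of view,
#' with named channels and plate/well/field provenance.  Channels are
#' 2-D numeric matrices of photon counts (0..65535); all channels of a
#' field share one shape.  The mitochondrial assay requires the channels
#' \code{nuclear} (Hoechst), \code{cytoplasm} (Calcein-AM) and
#' \code{mito} (TMRM); an optional \code{marker} channel carries an
#' immunostain used for differentiation QC.
#'
#' @slot channels named list of equal-shape numeric matrices.
#' @slot plateId character(1) plate identifier.
#' @slot well character(1) well in 384-well convention ("A1".."P24").
#' @slot fieldIndex integer(1), zero-based field index within the well.
#' @slot pixelSizeUm numeric(1) microns per pixel, or NA if unknown
#'   (measurements are then reported in pixels).
#'
#' @examples
#' spec <- syntheticFieldSpec(imageShape = c(64, 64), nCells = 3, seed = 1)
#' fld <- generateField(spec)$field
#' fld
#' channelNames(fld)
#' dim(channel(fld, "nuclear"))
#' @export
setClass("FieldImage",
  representation(
    channels = "list",
    plateId = "character",
    well = "character",
    fieldIndex = "integer",
    pixelSizeUm = "numeric"
  ),
  prototype(
    channels = list(), plateId = "plate", well = "A1",
    fieldIndex = 0L, pixelSizeUm = NA_real_
  )
)

setValidity("FieldImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("FieldImage must have at least one channel")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("all channels must be named")
  if (anyDuplicated(names(ch))) return("duplicate channel names")
  bad <- setdiff(names(ch), KNOWN_CHANNELS)
  if (length(bad))
    return(sprintf("unknown channel name(s): %s (expected %s)",
                   paste(bad, collapse = ", "),
                   paste(KNOWN_CHANNELS, collapse = ", ")))
  if (!all(vapply(ch, function(m) is.matrix(m) && is.numeric(m), logical(1))))
    return("all channels must be numeric matrices")
  dims <- vapply(ch, dim, integer(2))
  if (ncol(dims) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    return("all channel arrays must share one shape")
  if (any(vapply(ch, function(m) any(m < 0, na.rm = TRUE), logical(1))))
    return("intensities must be >= 0")
  if (length(object@well) != 1L || !isValidWell(object@well))
    return(sprintf("invalid 384-well name '%s'", object@well))
  if (length(object@fieldIndex) != 1L || object@fieldIndex < 0L)
    return("fieldIndex must be a single integer >= 0")
  TRUE
})

#' Construct a FieldImage
#'
#' @param channels named list of numeric matrices (counts); names among
#'   \code{nuclear}, \code{cytoplasm}, \code{mito}, \code{marker}.
#' @param plateId,well,fieldIndex provenance of the field.
#' @param pixelSizeUm optional microns/pixel metadata.
#' @return a \linkS4class{FieldImage}.
#' @export
FieldImage <- function(channels, plateId = "plate", well = "A1",
                       fieldIndex = 0L, pixelSizeUm = NA_real_) {
  new("FieldImage", channels = channels, plateId = plateId, well = well,
      fieldIndex = as.integer(fieldIndex), pixelSizeUm = pixelSizeUm)
}

#' Specification of one synthetic field
#'
#' Parameters of the synthetic-field generator.  Cells are nuclei
#' (Gaussian-blurred discs on the nuclear channel), live cells
#' additionally get a larger soma disc on the cytoplasmic channel and a
#' set of rotated bright ellipses (mitochondria) on the mitochondrial
#' channel whose amplitude scales with the per-cell membrane-potential
#' factor \code{tmrmScale} (1.0 = control basal).
#'
#' @slot imageShape integer(2) image shape (rows, cols).
#' @slot nCells integer(1) number of cells (or Poisson mean, see
#'   \code{nCellsPoisson}).
#' @slot nCellsPoisson logical(1); if TRUE, the realized cell count is
#'   drawn from Poisson(nCells).
#' @slot deadFraction numeric(1) in [0,1]: probability a cell is dead.
#' @slot nucleusRadiusPx,nucleusRadiusSd numeric(1) nucleus disc radius
#'   mean and sd (pixels).
#' @slot somaRadiusPx,somaRadiusSd numeric(1) soma disc radius mean and
#'   sd (pixels); mean must exceed the nucleus mean.
#' @slot mitoPerCell numeric(1) Poisson mean mitochondrion count per live cell.
#' @slot mitoLengthPx,mitoLengthSd numeric(1) mitochondrion full length
#'   mean and sd (pixels).
#' @slot mitoWidthPx numeric(1) mitochondrion full width (pixels).
#' @slot tmrmScale numeric(1) per-cell multiplicative factor on the
#'   mitochondrial-channel amplitude; proxies membrane potential.
#' @slot mitoCytoFraction numeric(1): amplitude of the diffuse cytosolic
#'   component of the potential-dependent stain, as a fraction of
#'   \code{mitoAmplitude} (also scaled by \code{tmrmScale}).
#' @slot markerFraction numeric(1) in [0,1] or NA: if not NA, a
#'   \code{marker} channel is generated in which this fraction of cells
#'   get a marker-positive soma.
#' @slot nuclearAmplitude,cytoAmplitude,mitoAmplitude numeric(1) peak
#'   signal amplitudes (counts) of the three stains.
#' @slot brightnessSdLog numeric(1) sdlog of the per-cell log-normal
#'   brightness factor (median 1).
#' @slot backgroundLevel numeric(1) background (counts).
#' @slot noiseSd numeric(1) Gaussian read-noise sd (counts); Poisson
#'   shot noise is applied to signal + background before read noise.
#' @slot blurSigma numeric(1) Gaussian blur sigma applied to the noise-free
#'   signal (pixels); models optical blur at the disc edges.
#' @slot minSeparationPx numeric(1) minimum distance between cell
#'   centers (pixels); default = soma mean radius.
#' @slot seed integer(1) RNG seed; generation is bit-reproducible.
#' @export
setClass("SyntheticFieldSpec",
  representation(
    imageShape = "integer", nCells = "integer", nCellsPoisson = "logical",
    deadFraction = "numeric",
    nucleusRadiusPx = "numeric", nucleusRadiusSd = "numeric",
    somaRadiusPx = "numeric", somaRadiusSd = "numeric",
    mitoPerCell = "numeric", mitoLengthPx = "numeric", mitoLengthSd = "numeric",
    mitoWidthPx = "numeric", tmrmScale = "numeric",
    mitoCytoFraction = "numeric", markerFraction = "numeric",
    nuclearAmplitude = "numeric", cytoAmplitude = "numeric",
    mitoAmplitude = "numeric", brightnessSdLog = "numeric",
    backgroundLevel = "numeric", noiseSd = "numeric", blurSigma = "numeric",
    minSeparationPx = "numeric", seed = "integer"
  )
)

setValidity("SyntheticFieldSpec", function(object) {
  chk <- function(cond, msg) if (!cond) msg else NULL
  msgs <- c(
    chk(length(object@imageShape) == 2L && all(object@imageShape >= 16L),
        "imageShape must be two integers >= 16"),
    chk(object@nCells >= 0L, "nCells must be >= 0"),
    chk(object@deadFraction >= 0 && object@deadFraction <= 1,
        "deadFraction must be in [0, 1]"),
    chk(object@nucleusRadiusPx > 0, "nucleusRadiusPx must be > 0"),
    chk(object@somaRadiusPx > 0, "somaRadiusPx must be > 0"),
    chk(object@somaRadiusPx > object@nucleusRadiusPx,
        "somaRadiusPx mean must exceed nucleusRadiusPx mean"),
    chk(object@mitoPerCell >= 0, "mitoPerCell must be >= 0"),
    chk(object@mitoLengthPx > 0, "mitoLengthPx must be > 0"),
    chk(object@mitoWidthPx > 0, "mitoWidthPx must be > 0"),
    chk(object@tmrmScale >= 0, "tmrmScale must be >= 0"),
    chk(object@mitoCytoFraction >= 0 && object@mitoCytoFraction <= 1,
        "mitoCytoFraction must be in [0, 1]"),
    chk(is.na(object@markerFraction) ||
          (object@markerFraction >= 0 && object@markerFraction <= 1),
        "markerFraction must be NA or in [0, 1]"),
    chk(object@backgroundLevel >= 0, "backgroundLevel must be >= 0"),
    chk(object@noiseSd >= 0, "noiseSd must be >= 0"),
    chk(object@minSeparationPx >= 0, "minSeparationPx must be >= 0")
  )
  if (length(msgs)) msgs[[1]] else TRUE
})

#' Construct a SyntheticFieldSpec
#'
#' Defaults emulate a 40x field of plated neurons in a 384-well screen:
#' ~50 cells per 512x512 field, 10% dead, nuclei of radius ~9 px inside
#' soma of radius ~20 px, ~8 punctate/elongated mitochondria per live
#' cell plus a faint diffuse cytosolic component of the
#' potential-dependent stain, 16-bit counts with background 50 and read
#' noise sd 10.
#'
#' @param imageShape,nCells,nCellsPoisson,deadFraction,nucleusRadiusPx,nucleusRadiusSd,somaRadiusPx,somaRadiusSd,mitoPerCell,mitoLengthPx,mitoLengthSd,mitoWidthPx,tmrmScale,mitoCytoFraction,markerFraction,nuclearAmplitude,cytoAmplitude,mitoAmplitude,brightnessSdLog,backgroundLevel,noiseSd,blurSigma,minSeparationPx,seed
#'   see the slot documentation of \linkS4class{SyntheticFieldSpec}.
#' @return a validated \linkS4class{SyntheticFieldSpec}.
#' @examples
#' syntheticFieldSpec(nCells = 10, deadFraction = 0.2, seed = 42)
#' @export
syntheticFieldSpec <- function(imageShape = c(512L, 512L),
                               nCells = 50L,
                               nCellsPoisson = FALSE,
                               deadFraction = 0.1,
                               nucleusRadiusPx = 9, nucleusRadiusSd = 1,
                               somaRadiusPx = 20, somaRadiusSd = 2,
                               mitoPerCell = 8,
                               mitoLengthPx = 7, mitoLengthSd = 2,
                               mitoWidthPx = 2,
                               tmrmScale = 1.0,
                               mitoCytoFraction = 0.1,
                               markerFraction = NA_real_,
                               nuclearAmplitude = 12000,
                               cytoAmplitude = 3000,
                               mitoAmplitude = 4000,
                               brightnessSdLog = 0.25,
                               backgroundLevel = 50,
                               noiseSd = 10,
                               blurSigma = 0.8,
                               minSeparationPx = somaRadiusPx,
                               seed = 1L) {
  new("SyntheticFieldSpec",
      imageShape = as.integer(imageShape), nCells = as.integer(nCells),
      nCellsPoisson = nCellsPoisson, deadFraction = deadFraction,
      nucleusRadiusPx = nucleusRadiusPx, nucleusRadiusSd = nucleusRadiusSd,
      somaRadiusPx = somaRadiusPx, somaRadiusSd = somaRadiusSd,
      mitoPerCell = mitoPerCell, mitoLengthPx = mitoLengthPx,
      mitoLengthSd = mitoLengthSd, mitoWidthPx = mitoWidthPx,
      tmrmScale = tmrmScale, mitoCytoFraction = mitoCytoFraction,
      markerFraction = markerFraction,
      nuclearAmplitude = nuclearAmplitude, cytoAmplitude = cytoAmplitude,
      mitoAmplitude = mitoAmplitude, brightnessSdLog = brightnessSdLog,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      blurSigma = blurSigma, minSeparationPx = minSeparationPx,
      seed = as.integer(seed))
}

#' Ground truth of a synthetic field
#'
#' @slot cells data.frame with one row per cell: \code{cell} (id),
#'   \code{row}, \code{col} (center, 0-based pixel coordinates),
#'   \code{live} (logical), \code{tmrmScale}, \code{nucleusRadius},
#'   \code{somaRadius}, \code{markerPositive}.
#' @slot mitochondria data.frame with one row per mitochondrion:
#'   \code{cell} (parent id), \code{row}, \code{col} (ellipse center),
#'   \code{semiMajor}, \code{semiMinor}, \code{theta} (radians).
#' @export
setClass("GroundTruth",
  representation(cells = "data.frame", mitochondria = "data.frame"))

setValidity("GroundTruth", function(object) {
  if (nrow(object@mitochondria)) {
    if (!all(object@mitochondria$cell %in% object@cells$cell))
      return("every mitochondrion's parent cell must exist")
    liveIds <- object@cells$cell[object@cells$live]
    if (!all(object@mitochondria$cell %in% liveIds))
      return("mitochondria may only belong to live cells")
  }
  TRUE
})

#' Nucleus/soma segmentation with live/dead classification
#'
#' @slot nuclei integer label matrix of nuclei (0 = background).
#' @slot soma integer label matrix of cell soma; soma labels equal their
#'   seeding nucleus labels and each soma contains its nucleus.
#' @slot liveIds integer vector of labels classified live.
#' @slot deadIds integer vector of labels classified dead (Calcein
#'   negative: soma area not exceeding the nucleus area).
#' @export
setClass("CellLabels",
  representation(nuclei = "matrix", soma = "matrix",
                 liveIds = "integer", deadIds = "integer"))

setValidity("CellLabels", function(object) {
  if (!identical(dim(object@nuclei), dim(object@soma)))
    return("nuclei and soma label maps must share one shape")
  nucIds <- sort(unique(as.integer(object@nuclei[object@nuclei > 0])))
  somaIds <- sort(unique(as.integer(object@soma[object@soma > 0])))
  if (!identical(nucIds, somaIds))
    return("soma label set must equal nucleus label set")
  if (length(intersect(object@liveIds, object@deadIds)))
    return("liveIds and deadIds must be disjoint")
  if (!identical(sort(c(object@liveIds, object@deadIds)), nucIds))
    return("liveIds and deadIds must partition the nucleus labels")
  if (any(object@soma[object@nuclei > 0] != object@nuclei[object@nuclei > 0]))
    return("each soma must contain its nucleus pixels")
  TRUE
})

#' Mitochondrial segmentation associated with cells
#'
#' @slot objects integer label matrix of individual mitochondria retained
#'   after assignment to live cells.
#' @slot merged integer label matrix in which touching mitochondria of
#'   the same cell are unified into one object (used for morphology).
#' @slot parent named integer vector mapping object label -> cell label.
#' @slot mergedParent named integer vector mapping merged label -> cell label.
#' @export
setClass("MitoLabels",
  representation(objects = "matrix", merged = "matrix",
                 parent = "integer", mergedParent = "integer"))

setValidity("MitoLabels", function(object) {
  objIds <- sort(unique(as.integer(object@objects[object@objects > 0])))
  if (!all(objIds %in% as.integer(names(object@parent))))
    return("every retained mitochondrion must have a parent cell")
  if (sum(object@objects > 0) != sum(object@merged > 0))
    return("merging must conserve mitochondrial pixels")
  TRUE
})

#' Plate layout: well -> (cell line, treatment, control-basal flag)
#'
#' @slot plateId character(1).
#' @slot wells data.frame with columns \code{well}, \code{cell_line},
#'   \code{treatment}, \code{control_basal} (logical).
#' @export
setClass("PlateLayout",
  representation(plateId = "character", wells = "data.frame"))

setValidity("PlateLayout", function(object) {
  w <- object@wells
  need <- c("well", "cell_line", "treatment", "control_basal")
  if (!all(need %in% names(w)))
    return(sprintf("layout must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(w$well))
    return(sprintf("duplicate well entry: %s",
                   paste(unique(w$well[duplicated(w$well)]), collapse = ", ")))
  bad <- w$well[!vapply(w$well, isValidWell, logical(1))]
  if (length(bad))
    return(sprintf("invalid 384-well name(s): %s", paste(bad, collapse = ", ")))
  TRUE
})

## ---- accessors ----

#' @describeIn FieldImage names of the channels present.
#' @param x,object a FieldImage.
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn FieldImage extract one channel matrix by role name.
#' @param name channel name.
#' @export
channel <- function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(x@channels), collapse = ", ")), call. = FALSE)
  x@channels[[name]]
}

#' @describeIn CellLabels nucleus label matrix.
#' @param x a CellLabels.
#' @export
nucleiLabels <- function(x) x@nuclei

#' @describeIn CellLabels soma label matrix.
#' @export
somaLabels <- function(x) x@soma

#' @describeIn CellLabels labels of live cells.
#' @export
liveIds <- function(x) x@liveIds

#' @describeIn CellLabels labels of dead (Calcein-negative) cells.
#' @export
deadIds <- function(x) x@deadIds

#' @describeIn PlateLayout wells table of a layout.
#' @param x a PlateLayout.
#' @export
layoutWells <- function(x) x@wells

#' @describeIn GroundTruth per-cell truth table.
#' @param x a GroundTruth.
#' @export
truthCells <- function(x) x@cells

#' @describeIn GroundTruth per-mitochondrion truth table.
#' @export
truthMitochondria <- function(x) x@mitochondria

## ---- show methods ----

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("FieldImage %s/%s field %d: %dx%d px, channels: %s\n",
              object@plateId, object@well, object@fieldIndex, d[1], d[2],
              paste(names(object@channels), collapse = ", ")))
  if (!is.na(object@pixelSizeUm))
    cat(sprintf("  pixel size: %g um\n", object@pixelSizeUm))
})

setMethod("show", "SyntheticFieldSpec", function(object) {
  cat(sprintf(paste0(
    "SyntheticFieldSpec: %dx%d px, %d cells%s, dead fraction %.2f\n",
    "  nucleus r = %g±%g px, soma r = %g±%g px\n",
    "  mito/cell = %g, length %g±%g px, width %g px, tmrmScale = %g\n",
    "  background %g, read noise sd %g, seed %d\n"),
    object@imageShape[1], object@imageShape[2], object@nCells,
    if (object@nCellsPoisson) " (Poisson mean)" else "",
    object@deadFraction,
    object@nucleusRadiusPx, object@nucleusRadiusSd,
    object@somaRadiusPx, object@somaRadiusSd,
    object@mitoPerCell, object@mitoLengthPx, object@mitoLengthSd,
    object@mitoWidthPx, object@tmrmScale,
    object@backgroundLevel, object@noiseSd, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells (%d live), %d mitochondria\n",
              nrow(object@cells), sum(object@cells$live),
              nrow(object@mitochondria)))
})

setMethod("show", "CellLabels", function(object) {
  cat(sprintf("CellLabels: %d cells (%d live, %d dead), %dx%d px\n",
              length(object@liveIds) + length(object@deadIds),
              length(object@liveIds), length(object@deadIds),
              nrow(object@nuclei), ncol(object@nuclei)))
})

setMethod("show", "MitoLabels", function(object) {
  cat(sprintf("MitoLabels: %d objects, %d merged objects, %d parent cells\n",
              length(object@parent), length(object@mergedParent),
              length(unique(object@parent))))
})

setMethod("show", "PlateLayout", function(object) {
  w <- object@wells
  cat(sprintf("PlateLayout '%s': %d wells (%d control-basal)\n",
              object@plateId, nrow(w), sum(w$control_basal)))
  print(head(w, 6))
  if (nrow(w) > 6) cat(sprintf("  ... and %d more wells\n", nrow(w) - 6L))
})
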