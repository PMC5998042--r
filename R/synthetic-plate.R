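# Whole-plate synthesis: many wells x fields written to disk with
# ground-truth tables, deterministically derived from one master seed.

#' Generate a synthetic plate on disk
#'
#' Writes, for every well and field, one 16-bit TIFF per channel (naming
#' convention of \code{\link{fieldFileName}}), a plate layout YAML, and
#' ground-truth tables \code{cells.csv} / \code{mitochondria.csv}.  The
#' per-field seed is a deterministic hash of (master seed, well, field),
#' so regeneration with the same master seed is byte-identical and
#' fields can be generated in any order.
#'
#' @param dir output directory (created if missing).
#' @param wellSpecs named list mapping well names (384-well convention,
#'   "A1".."P24") to \linkS4class{SyntheticFieldSpec} objects.
#' @param fieldsPerWell integer: fields imaged per well.
#' @param plateId plate identifier used in file names.
#' @param masterSeed integer master seed.
#' @param layout optional \linkS4class{PlateLayout}; written alongside
#'   the images as \code{layout.yaml} when given.
#' @return invisibly, a list with \code{cells} and \code{mitochondria}
#'   ground-truth data.frames (with plate/well/field columns) and the
#'   vector of written image \code{files}.
#' @examples
#' \donttest{
#' d <- file.path(tempdir(), "plate")
#' spec <- syntheticFieldSpec(imageShape = c(96, 96), nCells = 4)
#' truth <- generatePlate(d, list(A1 = spec, B2 = spec), fieldsPerWell = 2)
#' nrow(truth$cells)
#' }
#' @export
generatePlate <- function(dir, wellSpecs, fieldsPerWell = 5L,
                          plateId = "simplate", masterSeed = 1L,
                          layout = NULL) {
  if (is.null(names(wellSpecs)) || any(!nzchar(names(wellSpecs))))
    stop("wellSpecs must be a named list (well -> SyntheticFieldSpec)",
         call. = FALSE)
  bad <- names(wellSpecs)[!vapply(names(wellSpecs), isValidWell, logical(1))]
  if (length(bad))
    stop(sprintf("validation error: invalid 384-well name(s): %s (A1..P24)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  allCells <- list()
  allMito <- list()
  files <- character(0)
  for (well in names(wellSpecs)) {
    spec <- wellSpecs[[well]]
    stopifnot(is(spec, "SyntheticFieldSpec"))
    for (f in seq_len(fieldsPerWell) - 1L) {
      spec@seed <- deriveSeed(masterSeed, normalizeWell(well), f)
      out <- generateField(spec, plateId = plateId,
                           well = normalizeWell(well), fieldIndex = f)
      files <- c(files, writeField(out$field, dir))
      tc <- truthCells(out$truth)
      tm <- truthMitochondria(out$truth)
      if (nrow(tc)) {
        tc <- cbind(plate_id = plateId, well = normalizeWell(well),
                    field = f, tc)
        allCells[[length(allCells) + 1L]] <- tc
      }
      if (nrow(tm)) {
        tm <- cbind(plate_id = plateId, well = normalizeWell(well),
                    field = f, tm)
        allMito[[length(allMito) + 1L]] <- tm
      }
    }
  }
  cells <- if (length(allCells)) do.call(rbind, allCells) else
    cbind(plate_id = character(0), well = character(0),
          field = integer(0), emptyTruthCells())
  mito <- if (length(allMito)) do.call(rbind, allMito) else
    cbind(plate_id = character(0), well = character(0),
          field = integer(0), emptyTruthMito())
  data.table::fwrite(cells, file.path(dir, "cells.csv"), na = "")
  data.table::fwrite(mito, file.path(dir, "mitochondria.csv"), na = "")
  if (!is.null(layout)) writePlateLayout(layout, file.path(dir, "layout.yaml"))
  invisible(list(cells = cells, mitochondria = mito, files = files))
}
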