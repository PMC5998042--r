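# Reading and writing field images, plate layouts and cell tables.
#
# Filename convention: <plate>_<well>_f<field>_<channel>.tif, one 16-bit
# grayscale single-page TIFF per channel. Coordinates are 0-based
# (row, col) with the pixel-center convention; images are stored as
# 16-bit unsigned integers, internal arithmetic is floating point.

#' File name for one channel of one field
#'
#' @param plateId,well,fieldIndex field provenance.
#' @param channelName one of nuclear, cytoplasm, mito, marker.
#' @return the file name (no directory).
#' @export
fieldFileName <- function(plateId, well, fieldIndex, channelName) {
  sprintf("%s_%s_f%d_%s.tif", plateId, well, as.integer(fieldIndex),
          channelName)
}

#' Write a FieldImage as per-channel 16-bit TIFF files
#'
#' @param field a \linkS4class{FieldImage}.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
writeField <- function(field, dir) {
  validObject(field)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in channelNames(field)) {
    path <- file.path(dir, fieldFileName(field@plateId, field@well,
                                         field@fieldIndex, nm))
    m <- clip16(round(channel(field, nm)))
    tiff::writeTIFF(m / MAX_COUNT, path, bits.per.sample = 16L,
                    compression = "none")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Load a FieldImage from per-channel TIFF files
#'
#' @param dir directory holding the channel files.
#' @param plateId,well,fieldIndex field identity (selects the files via
#'   the naming convention, see \code{\link{fieldFileName}}).
#' @param channels channel roles to load.
#' @param pixelSizeUm optional microns/pixel metadata to attach.
#' @return a \linkS4class{FieldImage} with integer-valued count matrices.
#' @export
loadField <- function(dir, plateId, well, fieldIndex,
                      channels = REQUIRED_CHANNELS, pixelSizeUm = NA_real_) {
  chans <- list()
  for (nm in channels) {
    path <- file.path(dir, fieldFileName(plateId, well, fieldIndex, nm))
    if (!file.exists(path))
      stop(sprintf("missing input: channel '%s' file not found: %s",
                   nm, path), call. = FALSE)
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (!is.matrix(m))
      stop(sprintf("format error: %s is not a single-page grayscale TIFF",
                   path), call. = FALSE)
    chans[[nm]] <- matrix(as.numeric(m), nrow(m), ncol(m))
  }
  dims <- vapply(chans, dim, integer(2))
  if (ncol(dims) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stop(sprintf("format error: channel shapes differ for %s/%s field %d",
                 plateId, well, fieldIndex), call. = FALSE)
  FieldImage(chans, plateId = plateId, well = well,
             fieldIndex = fieldIndex, pixelSizeUm = pixelSizeUm)
}

#' Parse a plate-layout YAML file
#'
#' The layout maps wells to cell line, treatment and the control-basal
#' flag used for normalization:
#' \preformatted{
#' plate_id: plate1
#' wells:
#'   A1: {cell_line: Control1, treatment: basal, control_basal: true}
#'   A2: {cell_line: Patient1, treatment: basal}
#' }
#'
#' @param path YAML file path.
#' @return a \linkS4class{PlateLayout}.
#' @export
parsePlateLayout <- function(path) {
  if (!file.exists(path))
    stop(sprintf("missing input: layout file not found: %s", path),
         call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop(sprintf("layout validation error in %s: %s", path,
                 conditionMessage(e)), call. = FALSE))
  plateLayoutFromList(doc, context = path)
}

# Build and validate a PlateLayout from a parsed config list.
plateLayoutFromList <- function(doc, context = "layout") {
  known <- c("plate_id", "wells")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop(sprintf("layout validation error in %s: unknown key(s): %s",
                 context, paste(extra, collapse = ", ")), call. = FALSE)
  if (is.null(doc$wells) || !length(doc$wells))
    stop(sprintf("layout validation error in %s: no wells defined", context),
         call. = FALSE)
  wellKnown <- c("cell_line", "treatment", "control_basal")
  rows <- lapply(names(doc$wells), function(w) {
    if (!isValidWell(w))
      stop(sprintf(
        "layout validation error in %s: invalid 384-well name '%s' (A1..P24)",
        context, w), call. = FALSE)
    entry <- doc$wells[[w]]
    bad <- setdiff(names(entry), wellKnown)
    if (length(bad))
      stop(sprintf("layout validation error in %s, well %s: unknown key(s): %s",
                   context, w, paste(bad, collapse = ", ")), call. = FALSE)
    data.frame(well = normalizeWell(w),
               cell_line = as.character(entry$cell_line %||% NA_character_),
               treatment = as.character(entry$treatment %||% NA_character_),
               control_basal = isTRUE(entry$control_basal))
  })
  wells <- do.call(rbind, rows)
  if (anyDuplicated(wells$well))
    stop(sprintf("layout validation error in %s: duplicate well entry: %s",
                 context,
                 paste(unique(wells$well[duplicated(wells$well)]),
                       collapse = ", ")), call. = FALSE)
  new("PlateLayout", plateId = as.character(doc$plate_id %||% "plate"),
      wells = wells)
}

#' Write a PlateLayout to YAML
#'
#' @param layout a \linkS4class{PlateLayout}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePlateLayout <- function(layout, path) {
  validObject(layout)
  wells <- setNames(lapply(seq_len(nrow(layout@wells)), function(i) {
    r <- layout@wells[i, ]
    e <- list(cell_line = r$cell_line, treatment = r$treatment)
    if (isTRUE(r$control_basal)) e$control_basal <- TRUE
    e
  }), layout@wells$well)
  yaml::write_yaml(list(plate_id = layout@plateId, wells = wells), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical CellRecord column order and types.
CELL_RECORD_COLUMNS <- c(
  plate_id = "character", well = "character", field = "integer",
  cell = "integer", cell_line = "character", treatment = "character",
  live = "logical", nucleus_area_px = "integer", cell_area_px = "integer",
  mean_intensity_cell = "numeric", mean_intensity_mito = "numeric",
  n_mito = "integer", mean_mito_area_px = "numeric",
  total_mito_area_fraction = "numeric", aspect_ratio = "numeric",
  major_axis_len_px = "numeric")

#' Write / read a per-cell measurement table (CSV)
#'
#' One row per cell, stable column order, missing values as empty cells.
#' Numeric fields are written with 17 significant digits so the
#' round-trip is lossless at double precision.
#'
#' @param records data.frame of cell records (see
#'   \code{\link{measureCells}} for the column panel).
#' @param path CSV file path.
#' @return \code{writeCellTable}: invisibly, \code{path};
#'   \code{readCellTable}: the records data.frame.
#' @export
writeCellTable <- function(records, path) {
  miss <- setdiff(names(CELL_RECORD_COLUMNS), names(records))
  for (m in miss) records[[m]] <- rep(NA, nrow(records))
  out <- records[, names(CELL_RECORD_COLUMNS), drop = FALSE]
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           sprintf("%.17g", out[[col]]))
  }
  data.table::fwrite(out, path, na = "", quote = "auto")
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: cell table not found: %s", path), call. = FALSE)
  cls <- unname(CELL_RECORD_COLUMNS)
  dt <- data.table::fread(path, colClasses = setNames(cls,
                          names(CELL_RECORD_COLUMNS)), na.strings = "")
  as.data.frame(dt)
}
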