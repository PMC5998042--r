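# Stage runners tying the pipeline together behind one YAML config.
# Subcommand semantics: simulate | segment | measure | analyze | markers.
# All randomness flows from master_seed; reruns with the same config and
# inputs produce identical tables.

#' Read and validate a run configuration
#'
#' The configuration is one YAML file with sections:
#' \preformatted{
#' paths: {input: imgs, output: out, layout: layout.yaml}
#' master_seed: 1
#' segmentation: {nucleus_min_area_px: 80, declump: watershed,
#'                lambda: 0.05, border_policy: keep}
#' mitochondria: {tophat_radius_px: 3, fixed_threshold: 120,
#'                mito_min_area_px: 2}
#' analysis: {min_cells_per_image: 5, center: median}
#' simulate: {plate_id: simplate, fields_per_well: 5,
#'            image_shape: [512, 512], n_cells: 50,
#'            wells: {A1: {cell_line: Control1, treatment: basal,
#'                         control_basal: true, tmrm_scale: 1.0}}}
#' }
#' Well entries under \code{simulate.wells} accept any
#' \code{\link{syntheticFieldSpec}} argument (snake_case) as a per-well
#' override of the field defaults given at the \code{simulate} level.
#'
#' @param path YAML config file.
#' @return a validated config list with parameter objects attached.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("missing input: config file not found: %s", path),
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("paths", "master_seed", "segmentation", "mitochondria",
             "analysis", "simulate")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop(sprintf("config validation error: unknown section(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  cfg$master_seed <- as.integer(cfg$master_seed %||% 1L)
  seg <- cfg$segmentation %||% list()
  cfg$segParams <- segmentationParams(
    nucleusMinAreaPx = seg$nucleus_min_area_px %||% 80L,
    declump = seg$declump %||% "watershed",
    lambda = seg$lambda %||% 0.05,
    borderPolicy = seg$border_policy %||% "keep",
    minCalceinIntensity = seg$min_calcein_intensity %||% NA_real_)
  mp <- cfg$mitochondria %||% list()
  cfg$mitParams <- mitoParams(
    tophatRadiusPx = mp$tophat_radius_px %||% 3L,
    fixedThreshold = mp$fixed_threshold %||% 120,
    mitoMinAreaPx = mp$mito_min_area_px %||% 2L,
    assignMethod = mp$assign_method %||% "centroid")
  an <- cfg$analysis %||% list()
  cfg$minCellsPerImage <- as.integer(an$min_cells_per_image %||% 5L)
  cfg$center <- an$center %||% "median"
  cfg$configPath <- normalizePath(path)
  cfg
}

# snake_case simulate-section entries -> syntheticFieldSpec arguments
specFromConfig <- function(defaults, override = list()) {
  take <- function(key, fallback) {
    override[[key]] %||% defaults[[key]] %||% fallback
  }
  syntheticFieldSpec(
    imageShape = unlist(take("image_shape", c(512L, 512L))),
    nCells = take("n_cells", 50L),
    nCellsPoisson = isTRUE(take("n_cells_poisson", FALSE)),
    deadFraction = take("dead_fraction", 0.1),
    nucleusRadiusPx = take("nucleus_radius_px", 9),
    nucleusRadiusSd = take("nucleus_radius_sd", 1),
    somaRadiusPx = take("soma_radius_px", 20),
    somaRadiusSd = take("soma_radius_sd", 2),
    mitoPerCell = take("mito_per_cell", 8),
    mitoLengthPx = take("mito_length_px", 7),
    mitoLengthSd = take("mito_length_sd", 2),
    mitoWidthPx = take("mito_width_px", 2),
    tmrmScale = take("tmrm_scale", 1.0),
    mitoCytoFraction = take("mito_cyto_fraction", 0.1),
    markerFraction = take("marker_fraction", NA_real_),
    backgroundLevel = take("background_level", 50),
    noiseSd = take("noise_sd", 10),
    minSeparationPx = take("min_separation_px",
                           take("soma_radius_px", 20)))
}

# Copy of the config + seed + versions + input checksums, written next
# to every stage's outputs for provenance.
writeRunManifest <- function(outDir, cfg, inputFiles = character(0)) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifest <- list(
    master_seed = cfg$master_seed,
    package_version = as.character(packageVersion("mitoHCS")),
    r_version = as.character(getRversion()),
    config = readLines(cfg$configPath),
    input_checksums = as.list(tools::md5sum(inputFiles)))
  yaml::write_yaml(manifest, file.path(outDir, "run_manifest.yaml"))
  file.copy(cfg$configPath, file.path(outDir, "config.yaml"),
            overwrite = TRUE)
  invisible(manifest)
}

# Discover (well, field) pairs present in an image directory for a plate.
discoverFields <- function(dir, plateId) {
  pat <- sprintf("^%s_([A-P]\\d{1,2})_f(\\d+)_nuclear\\.tif$", plateId)
  files <- list.files(dir)
  hits <- regmatches(files, regexec(pat, files))
  hits <- hits[lengths(hits) == 3]
  if (!length(hits))
    stop(sprintf("missing input: no '%s_*_f*_nuclear.tif' files in %s",
                 plateId, dir), call. = FALSE)
  df <- data.frame(well = vapply(hits, `[`, character(1), 2),
                   field = as.integer(vapply(hits, `[`, character(1), 3)))
  df[order(df$well, df$field), , drop = FALSE]
}

#' Run pipeline stages from a configuration
#'
#' \code{runSimulate} writes a synthetic plate (images, ground truth,
#' layout) into \code{paths$input}.  \code{runSegment} segments every
#' field, writing label maps (16-bit TIFF) and the per-cell table.
#' \code{runMeasure} writes the full per-cell readout panel
#' (\code{cell_records.csv}).  \code{runAnalyze} aggregates per image,
#' normalizes to control-basal and writes the statistics report.
#' \code{runMarkers} computes marker positivity per field.  Each stage
#' writes a run manifest (config copy, seed, versions, input checksums)
#' into its output directory.
#'
#' @param cfg config list from \code{\link{readRunConfig}} (or a path).
#' @return the stage's main table (or file list), invisibly where the
#'   side effect is the point.
#' @export
runSimulate <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  sim <- cfg$simulate
  if (is.null(sim) || is.null(sim$wells))
    stop("config validation error: simulate.wells is required", call. = FALSE)
  dir <- cfg$paths$input %||% stop("config validation error: paths.input required",
                                   call. = FALSE)
  wellKeys <- c("cell_line", "treatment", "control_basal")
  wellSpecs <- lapply(sim$wells, function(entry)
    specFromConfig(sim, entry[setdiff(names(entry), wellKeys)]))
  names(wellSpecs) <- names(sim$wells)
  layout <- plateLayoutFromList(list(
    plate_id = sim$plate_id %||% "simplate",
    wells = lapply(sim$wells, function(e) e[intersect(names(e), wellKeys)])),
    context = "simulate.wells")
  res <- generatePlate(dir, wellSpecs,
                       fieldsPerWell = sim$fields_per_well %||% 5L,
                       plateId = sim$plate_id %||% "simplate",
                       masterSeed = cfg$master_seed, layout = layout)
  writeRunManifest(dir, cfg)
  invisible(res)
}

processPlateDir <- function(cfg, writeLabels = FALSE) {
  inDir <- cfg$paths$input %||% stop("config validation error: paths.input required",
                                     call. = FALSE)
  outDir <- cfg$paths$output %||% stop("config validation error: paths.output required",
                                       call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  layoutPath <- cfg$paths$layout %||% file.path(inDir, "layout.yaml")
  layout <- if (file.exists(layoutPath)) parsePlateLayout(layoutPath) else NULL
  plateId <- if (!is.null(layout)) layout@plateId else
    cfg$simulate$plate_id %||% "simplate"
  fields <- discoverFields(inDir, plateId)
  recs <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    fld <- loadField(inDir, plateId, fields$well[i], fields$field[i])
    res <- processField(fld, cfg$segParams, cfg$mitParams, layout)
    recs[[i]] <- res$records
    if (writeLabels) {
      base <- sprintf("%s_%s_f%d", plateId, fields$well[i], fields$field[i])
      for (what in c("nuclei", "soma")) {
        lab <- slot(res$cells, what)
        tiff::writeTIFF(clip16(lab) / MAX_COUNT,
                        file.path(outDir, sprintf("%s_labels_%s.tif", base, what)),
                        bits.per.sample = 16L, compression = "none")
      }
      tiff::writeTIFF(clip16(res$mito@merged) / MAX_COUNT,
                      file.path(outDir, sprintf("%s_labels_mito.tif", base)),
                      bits.per.sample = 16L, compression = "none")
    }
  }
  records <- do.call(rbind, recs)
  list(records = records, layout = layout, inDir = inDir, outDir = outDir)
}

#' @rdname runSimulate
#' @export
runSegment <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  res <- processPlateDir(cfg, writeLabels = TRUE)
  writeCellTable(res$records, file.path(res$outDir, "cell_records.csv"))
  writeRunManifest(res$outDir, cfg,
                   list.files(res$inDir, full.names = TRUE, pattern = "\\.tif$"))
  invisible(res$records)
}

#' @rdname runSimulate
#' @export
runMeasure <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  res <- processPlateDir(cfg, writeLabels = FALSE)
  writeCellTable(res$records, file.path(res$outDir, "cell_records.csv"))
  writeRunManifest(res$outDir, cfg,
                   list.files(res$inDir, full.names = TRUE, pattern = "\\.tif$"))
  invisible(res$records)
}

#' @rdname runSimulate
#' @export
runAnalyze <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  outDir <- cfg$paths$output %||% stop("config validation error: paths.output required",
                                       call. = FALSE)
  tablePath <- file.path(outDir, "cell_records.csv")
  records <- readCellTable(tablePath)
  layoutPath <- cfg$paths$layout %||%
    file.path(cfg$paths$input %||% ".", "layout.yaml")
  layout <- parsePlateLayout(layoutPath)
  summ <- aggregatePerImage(records, cfg$minCellsPerImage)
  norm <- normalizeToControl(summ, layout, center = cfg$center)
  report <- statsReport(norm)
  data.table::fwrite(summ, file.path(outDir, "image_summaries.csv"), na = "")
  data.table::fwrite(norm, file.path(outDir, "normalized_summaries.csv"),
                     na = "")
  data.table::fwrite(report, file.path(outDir, "stats_report.csv"), na = "")
  writeRunManifest(outDir, cfg, tablePath)
  invisible(list(summaries = summ, normalized = norm, report = report))
}

#' @rdname runSimulate
#' @export
runMarkers <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  inDir <- cfg$paths$input
  outDir <- cfg$paths$output %||% inDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  layoutPath <- cfg$paths$layout %||% file.path(inDir, "layout.yaml")
  layout <- if (file.exists(layoutPath)) parsePlateLayout(layoutPath) else NULL
  plateId <- if (!is.null(layout)) layout@plateId else
    cfg$simulate$plate_id %||% "simplate"
  fields <- discoverFields(inDir, plateId)
  rows <- lapply(seq_len(nrow(fields)), function(i) {
    fld <- loadField(inDir, plateId, fields$well[i], fields$field[i],
                     channels = c("nuclear", "marker"))
    data.frame(plate_id = plateId, well = fields$well[i],
               field = fields$field[i],
               pct_positive = markerPositivity(channel(fld, "nuclear"),
                                               channel(fld, "marker"),
                                               cfg$segParams))
  })
  tab <- do.call(rbind, rows)
  data.table::fwrite(tab, file.path(outDir, "marker_positivity.csv"), na = "")
  writeRunManifest(outDir, cfg,
                   list.files(inDir, full.names = TRUE, pattern = "\\.tif$"))
  invisible(tab)
}
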