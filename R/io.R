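#' @include groomConfig.R ethogram.R dustmaps.R
NULL

#' Read an ethogram from CSV
#'
#' Expects a header \code{iteration,label} (optionally followed by a
#' \code{subject_id} column) with 1-based, contiguous, duplicate-free
#' iterations.
#'
#' @param path CSV file path.
#' @param timestep timestep duration attached to the result.
#' @return an \linkS4class{Ethogram}.
#' @export
readEthogramCSV <- function(path, timestep = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("iteration", "label") %in% names(df)[1:2]))
    stop("ethogram CSV must start with columns 'iteration,label'")
  if (anyDuplicated(df$iteration)) stop("duplicate iterations in ", path)
  o <- order(df$iteration)
  df <- df[o, ]
  if (!identical(as.integer(df$iteration), seq_len(nrow(df))))
    stop("iterations must be contiguous and 1-based in ", path)
  subj <- if ("subject_id" %in% names(df)) unique(df$subject_id) else "subject"
  if (length(subj) != 1L) stop("a single ethogram CSV must have one subject_id")
  Ethogram(df$label, timestep = timestep, subjectId = subj)
}

#' Write an ethogram to CSV
#'
#' @param ethogram an \linkS4class{Ethogram}.
#' @param path output CSV path.
#' @param subjectColumn include a \code{subject_id} column.
#' @return the path, invisibly.
#' @export
writeEthogramCSV <- function(ethogram, path, subjectColumn = FALSE) {
  stopifnot(is(ethogram, "Ethogram"))
  df <- data.frame(iteration = seq_along(ethogram@labels),
                   label = ethogram@labels)
  if (subjectColumn) df$subject_id <- ethogram@subjectId
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write simulator configurations as YAML
#'
#' The YAML keys mirror the \linkS4class{GroomConfig} slot names exactly.
#'
#' @param path YAML file path.
#' @return [readGroomConfig()] returns a \linkS4class{GroomConfig};
#'   [writeGroomConfig()] returns the path invisibly.
#' @export
readGroomConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(groomConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(groomConfig, vals)
}

#' @rdname readGroomConfig
#' @param config a \linkS4class{GroomConfig}.
#' @export
writeGroomConfig <- function(config, path) {
  stopifnot(is(config, "GroomConfig"))
  vals <- list(
    mode = config@mode, nModules = config@nModules,
    sensoryWeights = config@sensoryWeights,
    inhibitionWeight = config@inhibitionWeight,
    dustBase = config@dustBase, dustNoise = config@dustNoise,
    dustRemoval = config@dustRemoval, nIterations = config@nIterations,
    seed = config@seed, clampedModules = config@clampedModules,
    clampValue = config@clampValue, uimRecurrence = config@uimRecurrence,
    legsEnabled = config@legsEnabled, legIncrement = config@legIncrement,
    legThreshold = config@legThreshold,
    legDustRemoval = config@legDustRemoval,
    anteriorBoundary = config@anteriorBoundary,
    moduleLabels = config@moduleLabels)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Write transition counts and probabilities as labeled CSV matrices
#'
#' @param tm a \linkS4class{TransitionMatrix}.
#' @param countsPath,probsPath output paths (either may be NULL to skip).
#' @return invisibly, the written paths.
#' @export
writeTransitionMatrixCSV <- function(tm, countsPath = NULL, probsPath = NULL) {
  stopifnot(is(tm, "TransitionMatrix"))
  if (!is.null(countsPath))
    utils::write.csv(as.data.frame(tm@counts), countsPath, row.names = TRUE)
  if (!is.null(probsPath))
    utils::write.csv(as.data.frame(tm@probabilities), probsPath, row.names = TRUE)
  invisible(c(countsPath, probsPath))
}

#' Export a transition graph as an edge list
#'
#' Writes \code{from,to,probability} rows for every transition whose
#' probability is at or above the display threshold (nonzero edges only), plus
#' a companion node table whose weights are the marginal bout fractions (node
#' radii in the published diagrams are proportional to these). The threshold
#' affects display only; the underlying matrix is untouched.
#'
#' @param tm a \linkS4class{TransitionMatrix}.
#' @param path output CSV path for the edge list.
#' @param minDisplay minimum displayed probability; defaults to the threshold
#'   stored on \code{tm}.
#' @param nodeWeights optional named numeric vector of marginal bout
#'   fractions; written to \code{<path>.nodes.csv} when given.
#' @return the edge-list path, invisibly.
#' @export
writeTransitionGraph <- function(tm, path, minDisplay = tm@minDisplay,
                                 nodeWeights = NULL) {
  stopifnot(is(tm, "TransitionMatrix"))
  idx <- which(tm@probabilities >= minDisplay & tm@probabilities > 0,
               arr.ind = TRUE)
  edges <- data.frame(from = tm@labels[idx[, 1L]],
                      to = tm@labels[idx[, 2L]],
                      probability = tm@probabilities[idx])
  edges <- edges[order(edges$from, edges$to), ]
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  if (!is.null(nodeWeights)) {
    nodes <- data.frame(label = names(nodeWeights), weight = unname(nodeWeights))
    utils::write.csv(nodes, paste0(path, ".nodes.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext))
}

.writeRaster <- function(values, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(values, path),
    tif = , tiff = tiff::writeTIFF(values, path, bits.per.sample = 8L),
    stop("unsupported raster format: ", ext))
  invisible(path)
}

#' Raster input/output for dust images, masks and maps
#'
#' Dust images and masks are written as 8-bit grayscale PNG or TIFF with the
#' 0/255 convention (binary 1 maps to full intensity) and binarized at 0.5 on
#' read. Dust maps are written both ways: as an 8-bit raster for visual
#' inspection (fractions scaled by 255) and losslessly as a CSV of fractions.
#'
#' @param path raster file (.png, .tif or .tiff).
#' @param ... annotation passed to [DustImage()].
#' @return the read object, or the written path invisibly.
#' @export
readDustImage <- function(path, ...) {
  binarize(.readRaster(path), cutoff = 0.5, ...)
}

#' @rdname readDustImage
#' @param image a \linkS4class{DustImage}.
#' @export
writeDustImage <- function(image, path) {
  stopifnot(is(image, "DustImage"))
  .writeRaster(image@pixels * 1.0, path)
}

#' @rdname readDustImage
#' @param regionName region label for the mask.
#' @export
readRegionMask <- function(path, regionName = "region") {
  raw <- .readRaster(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  RegionMask((raw > 0.5) * 1L, regionName = regionName)
}

#' @rdname readDustImage
#' @param map a \linkS4class{DustMap}.
#' @export
writeDustMap <- function(map, path) {
  stopifnot(is(map, "DustMap"))
  .writeRaster(map@fractions, path)
}

#' @rdname readDustImage
#' @export
writeDustMapCSV <- function(map, path) {
  stopifnot(is(map, "DustMap"))
  utils::write.table(map@fractions, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname readDustImage
#' @export
readDustMapCSV <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  new("DustMap", fractions = m, nSubjects = NA_integer_)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a command-line run bit-for-bit:
#' subcommand, full parameter echo, seed, output paths and package version.
#'
#' @param subcommand name of the executed subcommand.
#' @param params named list echoing all effective parameters.
#' @param seed integer seed of the run.
#' @param outputPaths character vector of files the run wrote.
#' @param path manifest output path (JSON).
#' @return the path, invisibly.
#' @export
writeRunManifest <- function(subcommand, params, seed, outputPaths, path) {
  manifest <- list(
    subcommand = subcommand,
    config_echo = params,
    seed = seed,
    output_paths = as.character(outputPaths),
    package_version = as.character(utils::packageVersion("groomSim")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
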