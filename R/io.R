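# Readers and writers for the pipeline's plain-text formats. CSV dialect:
# comma separator, "." decimal, UTF-8, missing values as empty fields,
# header row always present and validated on read.

writeCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
}

readCsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = "")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(basename(path), " lacks column(s): ",
         paste(missing, collapse = ", "))
  x
}

#' Write / read a plate-map CSV
#'
#' Columns: \code{plate_id}, \code{well} (letter + two-digit column,
#' \code{"A01"}), \code{content_class}, \code{sirna_id}, \code{gene_id}
#' (empty where absent). Reading validates well names, content classes
#' and duplicate (plate, well) pairs.
#'
#' @param layout layout data.frame (see \code{\link{buildScreenLayout}}).
#' @param path file path.
#' @return \code{readPlateMap} returns the validated layout with
#'   \code{row}/\code{col} columns restored; \code{writePlateMap} returns
#'   the path invisibly.
#' @export
writePlateMap <- function(layout, path) {
  cols <- c("plate_id", "well", "content_class", "sirna_id", "gene_id")
  writeCsv(layout[, cols], path)
  invisible(path)
}

#' @rdname writePlateMap
#' @param plateRows,plateCols expected plate geometry for validation.
#' @export
readPlateMap <- function(path, plateRows = 16L, plateCols = 24L) {
  x <- readCsv(path, c("plate_id", "well", "content_class", "sirna_id",
                       "gene_id"))
  x$sirna_id <- as.character(x$sirna_id)
  x$gene_id <- as.character(x$gene_id)
  validatePlateLayout(x, plateRows, plateCols)
  rc <- parseWellName(x$well)
  x$row <- rc$row
  x$col <- rc$col
  x
}

#' Write / read a per-well measurement CSV
#'
#' Columns: \code{plate_id}, \code{well}, \code{replicate},
#' \code{raw_value} (empty = missing), \code{n_nuclei}.
#'
#' @param wells well table data.frame.
#' @param path file path.
#' @export
writeWellTable <- function(wells, path) {
  cols <- intersect(c("plate_id", "well", "replicate", "raw_value",
                      "n_nuclei", "source"), names(wells))
  writeCsv(wells[, cols], path)
  invisible(path)
}

#' @rdname writeWellTable
#' @export
readWellTable <- function(path) {
  x <- readCsv(path, c("plate_id", "well", "replicate", "raw_value",
                       "n_nuclei"))
  parseWellName(x$well)
  x$raw_value <- as.numeric(x$raw_value)
  x$replicate <- as.integer(x$replicate)
  x$n_nuclei <- as.integer(x$n_nuclei)
  x
}

#' Write / read a spot coordinate CSV
#'
#' Columns: \code{image_id}, \code{cell_id}, \code{row}, \code{col}
#' (1-based pixel coordinates), \code{spot_class} (\code{"centromeric"}
#' or \code{"noncentromeric"}).
#'
#' @param spots spot table data.frame.
#' @param path file path.
#' @export
writeSpotTable <- function(spots, path) {
  writeCsv(spots, path)
  invisible(path)
}

#' @rdname writeSpotTable
#' @export
readSpotTable <- function(path) {
  x <- readCsv(path, c("cell_id", "row", "col", "spot_class"))
  bad <- setdiff(unique(x$spot_class), c("centromeric", "noncentromeric"))
  if (length(bad))
    stop("unknown spot_class: ", paste(bad, collapse = ", "))
  x$row <- as.integer(x$row)
  x$col <- as.integer(x$col)
  x
}

#' Write / read a single-channel grayscale TIFF
#'
#' The on-disk convention is 16-bit unsigned grayscale (values are
#' clipped to [0, 65535] and rounded; clipping is reported via a
#' warning). A 32-bit float variant is available where quantization to
#' integers must be avoided. Channel pairs of a well are conventionally
#' stored as \code{<stem>_dapi.tif} / \code{<stem>_yfp.tif}.
#'
#' @param img numeric matrix of intensities.
#' @param path file path.
#' @param bits 16 (integer, default) or 32 (float).
#' @export
writeChannelTiff <- function(img, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  if (bits == 16L) {
    if (any(img < 0) || any(img > 65535))
      warning("intensities clipped to the 16-bit range in ",
              basename(path))
    img <- round(pmin(pmax(img, 0), 65535))
  }
  tiff::writeTIFF(img / 65535, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname writeChannelTiff
#' @export
readChannelTiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x * 65535
}

#' Write / read a run configuration
#'
#' Run configurations are nested named lists (see
#' \code{\link{defaultRunConfig}}) serialized as YAML; the round trip
#' \code{readRunConfig(writeRunConfig(cfg))} reproduces the configuration
#' exactly. Every pipeline run writes its resolved configuration next to
#' its outputs.
#'
#' @param config named list.
#' @param path file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}
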