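# image_io: reading and writing angiogram TIFF/PNG rasters, binary masks,
# metadata sidecars, training annotations and measurement tables, plus the
# scan-quality exclusion filter.

readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read image '", path, "': file not found")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                       error = function(e)
                         stop("cannot read image '", path, "': ",
                              conditionMessage(e), call. = FALSE))
    if (length(frames) > 1L)
      stop("multi-frame TIFF '", path, "': frame choice is ambiguous, refusing")
    px <- frames[[1]]
    attributes(px) <- list(dim = dim(px))
    bitDepth <- if (max(px) > 255) 16L else 8L
    list(pixels = px, bitDepth = bitDepth)
  } else if (ext == "png") {
    px <- tryCatch(png::readPNG(path, info = TRUE),
                   error = function(e)
                     stop("cannot read image '", path, "': ",
                          conditionMessage(e), call. = FALSE))
    info <- attr(px, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    scaled <- roundHalfUp(px * (2^depth - 1))
    attributes(scaled) <- list(dim = dim(scaled))
    list(pixels = scaled, bitDepth = as.integer(depth))
  } else {
    stop("unsupported image format '", ext, "' for '", path,
         "' (TIFF or PNG expected)")
  }
}

#' Read an en-face angiogram image
#'
#' Reads a single-frame grayscale TIFF or PNG, coerces it to 8 bits with
#' [to8bit()] (identity for 8-bit input, occupied-range min-max scaling for
#' 16-bit, luminance for colour) and attaches the scan metadata unchanged.
#' Multi-frame TIFFs are rejected rather than silently taking the first
#' frame.
#'
#' @param path path to a TIFF or PNG file.
#' @param metadata optional [ScanMetadata-class].
#' @return An [Angiogram-class].
#' @export
readAngiogram <- function(path, metadata = NULL) {
  r <- readRaster(path)
  Angiogram(to8bit(r$pixels, bitDepth = r$bitDepth), metadata = metadata)
}

#' Scan-quality exclusion filter
#'
#' Partitions scan records by the device quality index: records with
#' `quality_index > minQualityExclusive` are kept, the rest excluded
#' (the conventional cut drops scans with quality index <= 15). Order is
#' preserved within each part.
#'
#' @param records a data.frame with a `quality_index` column, or a list whose
#'   elements are [ScanMetadata-class] objects (or lists carrying one under
#'   `$meta`).
#' @param minQualityExclusive integer threshold; records must exceed it to be
#'   kept. Default 15.
#' @return `list(kept = ..., excluded = ...)`, a partition of the input.
#' @export
filterQuality <- function(records, minQualityExclusive = 15L) {
  qi <- if (is.data.frame(records)) {
    if (!"quality_index" %in% names(records))
      stop("records must carry a quality_index column")
    records$quality_index
  } else {
    vapply(records, function(r) {
      if (is(r, "ScanMetadata")) return(as.numeric(r@qualityIndex))
      if (is.list(r) && is(r$meta, "ScanMetadata"))
        return(as.numeric(r$meta@qualityIndex))
      if (is.list(r) && !is.null(r$quality_index))
        return(as.numeric(r$quality_index))
      stop("record carries no quality index")
    }, numeric(1))
  }
  keep <- qi > minQualityExclusive
  if (is.data.frame(records)) {
    list(kept = records[keep, , drop = FALSE],
         excluded = records[!keep, , drop = FALSE])
  } else {
    list(kept = records[keep], excluded = records[!keep])
  }
}

#' Write / read a binary mask
#'
#' Masks are stored as 8-bit single-channel TIFF or PNG with values exactly
#' \{0, 255\}; writing then reading returns an identical pixel grid.
#'
#' @param mask a [BinaryMask-class].
#' @param path destination (`.tif`/`.tiff` or `.png`).
#' @return `writeMask` returns `path` invisibly; `readMask` a
#'   [BinaryMask-class].
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  img <- mask@pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else {
    stop("unsupported mask format '", ext, "' (TIFF or PNG expected)")
  }
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  r <- readRaster(path)
  px <- r$pixels
  if (!all(px %in% c(0, 255)))
    stop("'", path, "' is not a binary mask: values other than {0, 255} found")
  BinaryMask(px)
}

measurementColumns <- c("subject_id", "eye", "visit", "plexus", "method",
                        "pixel_count", "area_mm2")

#' Validate a measurement table
#'
#' A measurement table is a long-format data.frame with columns
#' `subject_id, eye, visit, plexus, method, pixel_count, area_mm2`;
#' `(subject_id, eye, visit, plexus, method)` must be a unique key, areas are
#' non-negative and an area is zero exactly when its pixel count is zero.
#'
#' @param table a data.frame.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validateMeasurements <- function(table) {
  missing <- setdiff(measurementColumns, names(table))
  if (length(missing))
    stop("measurement table lacks columns: ", paste(missing, collapse = ", "))
  if (!all(table$method %in% c("script", "ml", "truth")))
    stop("method must be 'script', 'ml' or 'truth'")
  key <- do.call(paste, c(table[c("subject_id", "eye", "visit", "plexus",
                                  "method")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (subject_id, eye, visit, plexus, method) records")
  if (any(table$area_mm2 < 0)) stop("area_mm2 must be non-negative")
  zeroMismatch <- xor(table$area_mm2 == 0, table$pixel_count == 0)
  if (any(zeroMismatch))
    stop("area_mm2 must be zero exactly when pixel_count is zero")
  invisible(table)
}

#' Write / read a measurement table
#'
#' Measurements are serialized as RFC-4180 CSV (UTF-8, header row) with
#' `area_mm2` printed at full double precision, so a round trip restores the
#' numbers bit-identically.
#'
#' @param table a valid measurement table (see [validateMeasurements()]).
#' @param path CSV destination.
#' @return `writeMeasurements` returns `path` invisibly; `readMeasurements`
#'   the table.
#' @export
writeMeasurements <- function(table, path) {
  validateMeasurements(table)
  out <- table[measurementColumns]
  out$area_mm2 <- sprintf("%.17g", out$area_mm2)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$visit <- as.integer(tab$visit)
  tab$pixel_count <- as.integer(tab$pixel_count)
  tab$area_mm2 <- as.numeric(tab$area_mm2)
  validateMeasurements(tab)
  tab
}

#' Read line-segment training annotations
#'
#' Annotations are a JSON array of objects
#' `{"image_id": str, "label": "vascular"|"avascular", "points": [[x,y],...]}`
#' with polylines in 0-based pixel coordinates of the 512 x 512 analysis
#' frame. Each polyline needs at least two vertices; unknown labels are
#' rejected.
#'
#' @param path path to the JSON file.
#' @return A list of annotations, each
#'   `list(imageId, label, points = n x 2 matrix)`.
#' @export
readAnnotations <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed annotation JSON '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(raw)) stop("annotation file must contain a JSON array")
  lapply(seq_along(raw), function(i) {
    a <- raw[[i]]
    if (is.null(a$label) || !a$label %in% c("vascular", "avascular"))
      stop("annotation ", i, ": unknown label '", a$label,
           "' (must be 'vascular' or 'avascular')")
    if (is.null(a$points) || length(a$points) < 2L)
      stop("annotation ", i, ": polyline needs at least 2 vertices")
    pts <- do.call(rbind, lapply(a$points, function(p) as.numeric(unlist(p))))
    if (ncol(pts) != 2L || anyNA(pts))
      stop("annotation ", i, ": points must be [x, y] pairs")
    list(imageId = if (is.null(a$image_id)) NA_character_
         else as.character(a$image_id),
         label = a$label, points = pts)
  })
}

#' Write training annotations
#'
#' Inverse of [readAnnotations()].
#'
#' @param annotations list as returned by [readAnnotations()].
#' @param path JSON destination.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
  out <- lapply(annotations, function(a)
    list(image_id = a$imageId, label = a$label,
         points = lapply(seq_len(nrow(a$points)),
                         function(i) as.numeric(a$points[i, ]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a metadata sidecar CSV
#'
#' The sidecar has columns
#' `file, subject_id, eye, visit, plexus, axial_length_mm, quality_index`,
#' keyed by image file name. Every row is validated against the
#' [ScanMetadata-class] invariants (visit 1..4, plexus SVP/IVP/DVP, axial
#' length in (15, 40) mm); invalid rows are rejected with an error naming the
#' row and field.
#'
#' @param path CSV path.
#' @return A data.frame, one validated row per scan.
#' @export
readMetadataCsv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "subject_id", "eye", "visit", "plexus",
            "axial_length_mm", "quality_index")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("metadata CSV lacks columns: ", paste(missing, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({
      ScanMetadata(tab$subject_id[i], tab$eye[i], tab$visit[i], tab$plexus[i],
                   tab$axial_length_mm[i], tab$quality_index[i])
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("metadata row ", i, " (file '", tab$file[i], "'): ", ok)
  }
  tab$visit <- as.integer(tab$visit)
  tab$quality_index <- as.integer(tab$quality_index)
  tab
}

# build a ScanMetadata from one sidecar row
metadataFromRow <- function(row) {
  ScanMetadata(row$subject_id, row$eye, row$visit, row$plexus,
               row$axial_length_mm, row$quality_index)
}
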