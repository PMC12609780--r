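#' Per-scan acquisition metadata
#'
#' Carries the acquisition context of one en-face angiogram: subject, eye,
#' visit (1 = preoperative baseline, 2-4 = postoperative follow-ups), vascular
#' plexus (SVP/IVP/DVP depth slab), axial length in mm (drives the
#' magnification correction) and the device scan-quality index (scans with
#' quality index <= 15 are conventionally excluded).
#'
#' @slot subjectId character scalar, opaque subject identifier.
#' @slot eye `"OD"` or `"OS"`.
#' @slot visit integer in 1..4.
#' @slot plexus one of `"SVP"`, `"IVP"`, `"DVP"`.
#' @slot axialLengthMm axial length in mm, must lie in (15, 40).
#' @slot qualityIndex non-negative integer scan quality index.
#' @export
setClass("ScanMetadata",
  representation(
    subjectId = "character",
    eye = "character",
    visit = "integer",
    plexus = "character",
    axialLengthMm = "numeric",
    qualityIndex = "integer"
  )
)

setValidity("ScanMetadata", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId) ||
      !nzchar(object@subjectId))
    msg <- c(msg, "invalid field 'subjectId': must be a non-empty string")
  if (length(object@eye) != 1L || !object@eye %in% c("OD", "OS"))
    msg <- c(msg, "invalid field 'eye': must be 'OD' or 'OS'")
  if (length(object@visit) != 1L || is.na(object@visit) ||
      !object@visit %in% 1:4)
    msg <- c(msg, "invalid field 'visit': must be an integer in 1..4")
  if (length(object@plexus) != 1L || !object@plexus %in% c("SVP", "IVP", "DVP"))
    msg <- c(msg, "invalid field 'plexus': must be 'SVP', 'IVP' or 'DVP'")
  if (length(object@axialLengthMm) != 1L || is.na(object@axialLengthMm) ||
      object@axialLengthMm <= 15 || object@axialLengthMm >= 40)
    msg <- c(msg, "invalid field 'axialLengthMm': must lie in (15, 40) mm")
  if (length(object@qualityIndex) != 1L || is.na(object@qualityIndex) ||
      object@qualityIndex < 0L)
    msg <- c(msg, "invalid field 'qualityIndex': must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' @param subjectId,eye,visit,plexus,axialLengthMm,qualityIndex see slots.
#' @return A `ScanMetadata` object.
#' @rdname ScanMetadata-class
#' @export
ScanMetadata <- function(subjectId, eye, visit, plexus, axialLengthMm,
                         qualityIndex) {
  new("ScanMetadata",
      subjectId = as.character(subjectId), eye = as.character(eye),
      visit = as.integer(visit), plexus = as.character(plexus),
      axialLengthMm = as.numeric(axialLengthMm),
      qualityIndex = as.integer(qualityIndex))
}

setClassUnion("ScanMetadataOrNULL", c("ScanMetadata", "NULL"))

#' 8-bit en-face angiogram with acquisition metadata
#'
#' An H x W grid of 8-bit intensities (flow signal; vessels bright, the FAZ
#' dark) plus optional [ScanMetadata-class]. Pixel coordinates used throughout
#' the package are 0-based, x rightward, y downward, pixel-centre convention;
#' a pixel (x, y) lives at matrix element `[y + 1, x + 1]`.
#'
#' @slot pixels integer matrix with values in 0..255 (rows = y, cols = x).
#' @slot metadata a [ScanMetadata-class] or `NULL`.
#' @export
setClass("Angiogram",
  representation(pixels = "matrix", metadata = "ScanMetadataOrNULL")
)

setValidity("Angiogram", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (length(px) == 0L) return("pixels must be non-empty")
  if (anyNA(px)) return("pixels must not contain NA")
  rng <- range(px)
  if (rng[1] < 0 || rng[2] > 255) return("pixel values must lie in [0, 255]")
  if (any(px != floor(px))) return("pixel values must be integers")
  TRUE
})

#' @param pixels,metadata see slots.
#' @return An `Angiogram`.
#' @rdname Angiogram-class
#' @export
Angiogram <- function(pixels, metadata = NULL) {
  storage.mode(pixels) <- "integer"
  new("Angiogram", pixels = pixels, metadata = metadata)
}

#' Binary raster mask
#'
#' Foreground/background raster sharing the grid of its source image.
#' Foreground is stored as 255 and background as 0 (white objects on black
#' background). `origin` records the (x, y) offset of the mask's (0, 0)
#' pixel relative to the source image it was derived from.
#'
#' @slot pixels matrix with values in \{0, 255\}.
#' @slot origin integer (x, y) offset in pixels.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", origin = "integer")
)

setValidity("BinaryMask", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (!all(px %in% c(0L, 255L))) return("mask values must be exactly 0 or 255")
  if (length(object@origin) != 2L || anyNA(object@origin))
    return("origin must be two integers")
  TRUE
})

#' @param pixels matrix; logical, \{0,1\} or \{0,255\} values are accepted and
#'   normalised to \{0,255\}.
#' @param origin integer (x, y) offset, default `c(0L, 0L)`.
#' @return A `BinaryMask`.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(pixels, origin = c(0L, 0L)) {
  if (is.logical(pixels)) {
    m <- matrix(0L, nrow(pixels), ncol(pixels))
    m[pixels] <- 255L
    pixels <- m
  } else {
    u <- unique(as.vector(pixels))
    if (all(u %in% c(0, 1))) pixels <- pixels * 255L
    storage.mode(pixels) <- "integer"
  }
  new("BinaryMask", pixels = pixels, origin = as.integer(origin))
}

#' Segmented FAZ region
#'
#' A connected avascular region in the 512 x 512 analysis frame: its binary
#' mask, foreground pixel count, traced outer boundary polygon, the
#' magnification-corrected area in mm^2 (NA until a scaling config and axial
#' length are applied) and the method that produced it.
#'
#' @slot mask a [BinaryMask-class] of the region.
#' @slot pixelCount number of foreground pixels.
#' @slot boundary n x 2 matrix of 0-based (x, y) outer-contour pixel centres.
#' @slot areaMm2 corrected area in mm^2, or `NA_real_`.
#' @slot method `"script"`, `"ml"` or `"truth"`.
#' @slot warnings character vector of per-region processing notes (for
#'   example a wand seed rescue).
#' @export
setClass("FazRegion",
  representation(
    mask = "BinaryMask",
    pixelCount = "integer",
    boundary = "matrix",
    areaMm2 = "numeric",
    method = "character",
    warnings = "character"
  )
)

setValidity("FazRegion", function(object) {
  msg <- character()
  if (object@pixelCount != sum(object@mask@pixels == 255L))
    msg <- c(msg, "pixelCount must equal the number of foreground mask pixels")
  if (!object@method %in% c("script", "ml", "truth"))
    msg <- c(msg, "method must be 'script', 'ml' or 'truth'")
  if (length(object@areaMm2) != 1L)
    msg <- c(msg, "areaMm2 must be a single number (possibly NA)")
  if (!is.na(object@areaMm2) && object@areaMm2 < 0)
    msg <- c(msg, "areaMm2 must be non-negative")
  if (length(msg)) msg else TRUE
})

FazRegion <- function(mask, method, boundary = NULL, areaMm2 = NA_real_,
                      warnings = character()) {
  if (is.null(boundary)) {
    boundary <- cpp_trace_boundary(mask01(mask))
  }
  new("FazRegion", mask = mask,
      pixelCount = sum(mask@pixels == 255L),
      boundary = boundary, areaMm2 = as.numeric(areaMm2),
      method = method, warnings = warnings)
}

#' Per-pixel texture feature stack
#'
#' Raw intensity plus windowed mean, median, variance and Shannon entropy
#' (bits, 256-bin histogram) at each radius, computed over square
#' (2r+1) x (2r+1) neighbourhoods with edge replication. One row per pixel in
#' R column-major order.
#'
#' @slot features numeric matrix, `prod(dim)` rows by `1 + 4 * length(radii)`
#'   columns.
#' @slot dim integer (H, W) of the source frame.
#' @slot featureNames column names of `features`.
#' @slot radii the window radii used, in pixels.
#' @export
setClass("FeatureStack",
  representation(
    features = "matrix",
    dim = "integer",
    featureNames = "character",
    radii = "integer"
  )
)

setValidity("FeatureStack", function(object) {
  msg <- character()
  if (ncol(object@features) != 1L + 4L * length(object@radii))
    msg <- c(msg, "feature count must be 1 + 4 * number of radii")
  if (length(object@featureNames) != ncol(object@features))
    msg <- c(msg, "featureNames must match feature columns")
  if (nrow(object@features) != prod(object@dim))
    msg <- c(msg, "feature rows must equal the number of pixels")
  if (length(msg)) msg else TRUE
})

#' Trained texture pixel classifier
#'
#' A random-forest pixel classifier together with the exact feature recipe it
#' was trained with (radii, feature names, expected frame size, tree count
#' and seed) and its training provenance. A saved model is applied to whole
#' datasets without further modification; [classifyImage()] refuses feature
#' stacks whose recipe does not match.
#'
#' @slot forest the fitted `ranger` ensemble.
#' @slot recipe list: `radii`, `features`, `nTrees`, `seed`, `frameDim`.
#' @slot classOrder the two class labels, `c("vascular", "avascular")`.
#' @slot provenance list: annotation hash, source image ids.
#' @slot trainAccuracy resubstitution accuracy on the training pixels.
#' @export
setClass("PixelClassifierModel",
  representation(
    forest = "ANY",
    recipe = "list",
    classOrder = "character",
    provenance = "list",
    trainAccuracy = "numeric"
  )
)

setValidity("PixelClassifierModel", function(object) {
  msg <- character()
  need <- c("radii", "features", "nTrees", "seed", "frameDim")
  if (!all(need %in% names(object@recipe)))
    msg <- c(msg, paste("recipe must contain:", paste(need, collapse = ", ")))
  if (length(object@classOrder) != 2L ||
      !setequal(object@classOrder, c("vascular", "avascular")))
    msg <- c(msg, "classOrder must be the labels 'vascular' and 'avascular'")
  if (length(msg)) msg else TRUE
})
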