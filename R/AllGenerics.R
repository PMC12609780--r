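#' Accessors for fazkit classes
#'
#' `pixels()` returns the raster matrix of an [Angiogram-class] or
#' [BinaryMask-class]; `scanMeta()` the attached [ScanMetadata-class];
#' `pixelCount()` the foreground pixel count of a [FazRegion-class];
#' `areaMm2()` / `areaMm2<-` the corrected area in mm^2;
#' `regionMask()` the region's [BinaryMask-class]; `boundaryPolygon()` its
#' traced outer contour; `segMethod()` which segmenter produced it.
#'
#' @param x an object.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("scanMeta", function(x) standardGeneric("scanMeta"))

#' @rdname accessors
#' @export
setGeneric("pixelCount", function(x) standardGeneric("pixelCount"))

#' @rdname accessors
#' @export
setGeneric("areaMm2", function(x) standardGeneric("areaMm2"))

#' @rdname accessors
#' @export
setGeneric("areaMm2<-", function(x, value) standardGeneric("areaMm2<-"))

#' @rdname accessors
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))

#' @rdname accessors
#' @export
setGeneric("boundaryPolygon", function(x) standardGeneric("boundaryPolygon"))

#' @rdname accessors
#' @export
setGeneric("segMethod", function(x) standardGeneric("segMethod"))

#' @rdname accessors
#' @export
setMethod("pixels", "Angiogram", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("scanMeta", "Angiogram", function(x) x@metadata)

#' @rdname accessors
#' @export
setMethod("pixelCount", "FazRegion", function(x) x@pixelCount)

#' @rdname accessors
#' @export
setMethod("areaMm2", "FazRegion", function(x) x@areaMm2)

#' @rdname accessors
#' @export
setMethod("areaMm2<-", "FazRegion", function(x, value) {
  x@areaMm2 <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setMethod("regionMask", "FazRegion", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("boundaryPolygon", "FazRegion", function(x) x@boundary)

#' @rdname accessors
#' @export
setMethod("segMethod", "FazRegion", function(x) x@method)

setMethod("show", "ScanMetadata", function(object) {
  cat(sprintf("ScanMetadata: subject %s, eye %s, visit %d, %s, AL %.2f mm, QI %d\n",
              object@subjectId, object@eye, object@visit, object@plexus,
              object@axialLengthMm, object@qualityIndex))
})

setMethod("show", "Angiogram", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Angiogram: %d x %d, 8-bit, range [%d, %d]\n",
              d[1], d[2], min(object@pixels), max(object@pixels)))
  if (!is.null(object@metadata)) show(object@metadata)
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryMask: %d x %d, %d foreground px, origin (%d, %d)\n",
              d[1], d[2], sum(object@pixels == 255L),
              object@origin[1], object@origin[2]))
})

setMethod("show", "FazRegion", function(object) {
  cat(sprintf("FazRegion [%s]: %d px, area %s mm^2\n", object@method,
              object@pixelCount,
              if (is.na(object@areaMm2)) "NA"
              else sprintf("%.4f", object@areaMm2)))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "FeatureStack", function(object) {
  cat(sprintf("FeatureStack: %d x %d frame, %d features (radii %s)\n",
              object@dim[1], object@dim[2], ncol(object@features),
              paste(object@radii, collapse = ", ")))
})

setMethod("show", "PixelClassifierModel", function(object) {
  cat(sprintf(
    "PixelClassifierModel: %d trees, seed %d, radii %s, train accuracy %.3f\n",
    object@recipe$nTrees, object@recipe$seed,
    paste(object@recipe$radii, collapse = ", "), object@trainAccuracy))
})
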