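# texture_segmenter: per-pixel texture features.

featureNamesFor <- function(radii) {
  c("intensity",
    as.vector(vapply(radii, function(r)
      paste0(c("mean", "median", "variance", "entropy"), "_r", r),
      character(4))))
}

#' Compute the per-pixel texture feature stack
#'
#' For every pixel and radius r, the mean, median, variance (n divisor) and
#' Shannon entropy (bits, 256-bin histogram of the full 8-bit range) of the
#' (2r+1) x (2r+1) square window centred on the pixel, with edge replication
#' at the borders, plus the raw intensity as the first feature. The dyadic
#' default radii cover capillary-scale to FAZ-scale texture.
#'
#' @param image 8-bit matrix or [Angiogram-class].
#' @param radii positive integer window radii.
#' @return A [FeatureStack-class].
#' @export
computeFeatures <- function(image, radii = c(1L, 2L, 4L, 8L, 16L)) {
  px <- asPixelMatrix(image)
  if (min(px) < 0 || max(px) > 255) stop("computeFeatures expects 8-bit input")
  radii <- as.integer(radii)
  if (any(radii < 1L)) stop("radii must be positive")
  m <- px
  storage.mode(m) <- "integer"
  stats <- cpp_window_stats(m, radii)
  feats <- cbind(as.numeric(m), stats)
  colnames(feats) <- featureNamesFor(radii)
  new("FeatureStack", features = feats,
      dim = c(nrow(px), ncol(px)), featureNames = colnames(feats),
      radii = radii)
}
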