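# script_segmenter: the full morphological FAZ pipeline, stage by stage.

#' Run the morphological FAZ segmentation pipeline
#'
#' Composes, in order: 8-bit conversion, (127, 127, 512, 512) crop, bilinear
#' resize to the 270 x 270 working frame (with averaging), Otsu binarization
#' with bright vessels as foreground, skeletonization, eight dilations, four
#' erosions, bilinear resize back to 512 x 512, and a zero-tolerance wand
#' flood fill at (255, 255) that selects the enclosed central avascular
#' region. The pipeline is deterministic: identical inputs give bit-identical
#' regions.
#'
#' @param angiogram an [Angiogram-class] (or plain matrix) at least
#'   `cropY + cropH` x `cropX + cropW` in size.
#' @param cfg a [scriptConfig()].
#' @param keepIntermediates if `TRUE`, return the per-stage images as well.
#' @return A [FazRegion-class] with `method = "script"` and the pixel count
#'   measured on the 512 x 512 frame, or, with `keepIntermediates = TRUE`,
#'   `list(region = FazRegion, intermediates = named list of stage outputs)`.
#' @export
runScriptPipeline <- function(angiogram, cfg = scriptConfig(),
                              keepIntermediates = FALSE) {
  px <- asPixelMatrix(angiogram)
  stages <- list()
  img8 <- to8bit(px)
  stages$`01_8bit` <- img8
  cropped <- centerCrop(img8, cfg)
  stages$`02_cropped` <- cropped
  work <- resizeBilinear(cropped, cfg$workSize, cfg$workSize,
                         averageOnDownscale = TRUE)
  stages$`03_downscaled` <- work
  ot <- otsuThreshold(work)
  if (ot$degenerate)
    stop("FAZ undefined: Otsu threshold is degenerate (constant image)")
  stages$`04_binary` <- ot$mask
  skel <- skeletonize(ot$mask)
  stages$`05_skeleton` <- skel
  dil <- dilateMask(skel, cfg$nDilate)
  stages$`06_dilated` <- dil
  ero <- erodeMask(dil, cfg$nErode)
  stages$`07_eroded` <- ero
  up <- resizeBilinear(ero@pixels, cfg$cropW, cfg$cropH,
                       averageOnDownscale = TRUE)
  stages$`08_upscaled` <- up
  wandInput <- if (cfg$thresholdBeforeWand) {
    m <- matrix(0L, nrow(up), ncol(up))
    m[up >= 128L] <- 255L
    m
  } else up
  wand <- wandRegion(wandInput, seed = cfg$wandSeed,
                     tolerance = cfg$wandTolerance,
                     rescueRadius = cfg$seedRescueRadius,
                     connectivity = cfg$wandConnectivity)
  stages$`09_region` <- wand$mask
  region <- FazRegion(wand$mask, method = "script", warnings = wand$warnings)
  if (keepIntermediates) list(region = region, intermediates = stages)
  else region
}

#' Write pipeline stage intermediates
#'
#' Writes the intermediates returned by
#' `runScriptPipeline(keepIntermediates = TRUE)` as numbered 8-bit TIFFs for
#' debugging.
#'
#' @param intermediates the `intermediates` list.
#' @param dir destination directory (created if needed).
#' @return The written paths, invisibly.
#' @export
writeIntermediates <- function(intermediates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(intermediates)) {
    obj <- intermediates[[nm]]
    px <- asPixelMatrix(obj)
    p <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(px / 255, p, bits.per.sample = 8L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
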