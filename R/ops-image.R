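# script_segmenter primitives: the stage operations of the morphological
# FAZ pipeline (8-bit conversion, crop, bilinear resize, Otsu threshold,
# thinning, dilation/erosion, wand flood fill).

#' Script pipeline configuration
#'
#' Stage parameters of the morphological FAZ pipeline: crop a 512 x 512
#' analysis frame at offset (127, 127), resize to a 270 x 270 working frame,
#' binarize with Otsu, skeletonize, dilate eight times, erode four times,
#' resize back to 512 x 512 and select the central avascular region with a
#' zero-tolerance wand at (255, 255).
#'
#' @param cropX,cropY,cropW,cropH analysis-frame crop rectangle (pixels).
#' @param workSize side of the square working frame for the morphology.
#' @param nDilate,nErode dilation / erosion iteration counts.
#' @param wandSeed 0-based (x, y) wand seed in the 512 x 512 frame.
#' @param wandTolerance intensity tolerance of the wand flood fill.
#' @param seedRescueRadius if the seed lands on a vessel pixel, search this
#'   radius (pixels, Euclidean) for the nearest dark pixel and re-seed there.
#' @param wandConnectivity 4 (default, conservative for an enclosed region)
#'   or 8.
#' @param thresholdBeforeWand if `TRUE`, binarize the upscaled image at 128
#'   before the wand instead of flood-filling the gray image directly.
#' @return A validated config list of class `fazScriptConfig`.
#' @export
scriptConfig <- function(cropX = 127L, cropY = 127L, cropW = 512L,
                         cropH = 512L, workSize = 270L, nDilate = 8L,
                         nErode = 4L, wandSeed = c(255L, 255L),
                         wandTolerance = 0L, seedRescueRadius = 10L,
                         wandConnectivity = 4L, thresholdBeforeWand = FALSE) {
  cfg <- list(cropX = as.integer(cropX), cropY = as.integer(cropY),
              cropW = as.integer(cropW), cropH = as.integer(cropH),
              workSize = as.integer(workSize), nDilate = as.integer(nDilate),
              nErode = as.integer(nErode), wandSeed = as.integer(wandSeed),
              wandTolerance = as.integer(wandTolerance),
              seedRescueRadius = as.integer(seedRescueRadius),
              wandConnectivity = as.integer(wandConnectivity),
              thresholdBeforeWand = isTRUE(thresholdBeforeWand))
  if (cfg$cropW <= 0L || cfg$cropH <= 0L) stop("crop extents must be positive")
  if (cfg$workSize < 3L) stop("workSize must be >= 3")
  if (cfg$nErode < 0L || cfg$nDilate < cfg$nErode)
    stop("need nDilate >= nErode >= 0")
  if (!cfg$wandConnectivity %in% c(4L, 8L))
    stop("wandConnectivity must be 4 or 8")
  class(cfg) <- "fazScriptConfig"
  cfg
}

#' Convert a raster to 8 bits
#'
#' 8-bit input is returned unchanged. 16-bit input is scaled linearly from
#' its occupied range onto \[0, 255\] (round half up); an image with zero
#' range maps to all zeros. A 3-channel colour array is converted to
#' luminance 0.299 R + 0.587 G + 0.114 B and rounded.
#'
#' @param pixels matrix (grayscale) or H x W x 3 array (colour).
#' @param bitDepth 8 or 16; if `NULL`, inferred (values above 255 imply 16).
#' @return An integer matrix with values in 0..255.
#' @export
to8bit <- function(pixels, bitDepth = NULL) {
  if (length(pixels) == 0L) stop("empty image")
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] < 3L) stop("colour image must have 3 channels")
    lum <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
    if (max(pixels) <= 1) lum <- lum * 255  # [0,1] float colour
    out <- roundHalfUp(lum)
    storage.mode(out) <- "integer"
    return(out)
  }
  if (is.null(bitDepth)) bitDepth <- if (max(pixels) > 255) 16L else 8L
  if (bitDepth == 8L) {
    out <- pixels
    storage.mode(out) <- "integer"
    return(out)
  }
  lo <- min(pixels); hi <- max(pixels)
  if (hi == lo) {
    out <- matrix(0L, nrow(pixels), ncol(pixels))
    return(out)
  }
  out <- roundHalfUp((pixels - lo) * 255 / (hi - lo))
  storage.mode(out) <- "integer"
  out
}

#' Crop the analysis frame
#'
#' Extracts the `cropW` x `cropH` rectangle at offset (`cropX`, `cropY`)
#' (0-based; output pixel (i, j) is source pixel (i + cropY, j + cropX)).
#' With the defaults this requires a source of at least 639 x 639.
#'
#' @param image matrix or [Angiogram-class].
#' @param cfg a [scriptConfig()].
#' @return Same type as the input, cropped.
#' @export
centerCrop <- function(image, cfg = scriptConfig()) {
  px <- asPixelMatrix(image)
  needH <- cfg$cropY + cfg$cropH
  needW <- cfg$cropX + cfg$cropW
  if (nrow(px) < needH || ncol(px) < needW)
    stop(sprintf("source %d x %d too small for crop: at least %d x %d required",
                 nrow(px), ncol(px), needH, needW))
  out <- px[(cfg$cropY + 1L):(cfg$cropY + cfg$cropH),
            (cfg$cropX + 1L):(cfg$cropX + cfg$cropW), drop = FALSE]
  if (is(image, "Angiogram")) Angiogram(out, metadata = image@metadata) else out
}

#' Bilinear resize with averaging on downscale
#'
#' Bilinear interpolation with pixel-centre mapping. When downscaling by an
#' integer factor of at least 2 and `averageOnDownscale` is `TRUE`, a box
#' mean over that factor is applied first (the resize "average" flag), which
#' prevents aliasing of thin vessels. Results are rounded half up back to
#' 8-bit integers unless `round = FALSE`.
#'
#' @param image matrix (any numeric values) or [Angiogram-class].
#' @param outW,outH target size in pixels.
#' @param averageOnDownscale apply the box prefilter when shrinking.
#' @param round round the result to integers (8-bit stage semantics).
#' @return A resized matrix (or [Angiogram-class] for Angiogram input).
#' @export
resizeBilinear <- function(image, outW, outH, averageOnDownscale = TRUE,
                           round = TRUE) {
  if (outW < 1 || outH < 1) stop("target size must be positive")
  px <- asPixelMatrix(image)
  out <- cpp_resize_bilinear(matrix(as.numeric(px), nrow(px), ncol(px)),
                             as.integer(outH), as.integer(outW),
                             isTRUE(averageOnDownscale))
  if (round) {
    out <- roundHalfUp(out)
    storage.mode(out) <- "integer"
  }
  if (is(image, "Angiogram")) Angiogram(out, metadata = image@metadata) else out
}

#' Otsu threshold
#'
#' Computes the 256-bin histogram threshold maximizing the between-class
#' variance and binarizes with bright ("white") objects as foreground:
#' pixels strictly above the threshold become 255. A constant image is
#' degenerate: an all-background mask is returned with `degenerate = TRUE`.
#'
#' @param image 8-bit matrix or [Angiogram-class].
#' @return `list(mask = BinaryMask, threshold = integer, degenerate = logical)`.
#' @export
otsuThreshold <- function(image) {
  px <- asPixelMatrix(image)
  if (min(px) < 0 || max(px) > 255) stop("otsuThreshold expects 8-bit input")
  counts <- as.numeric(tabulate(as.vector(px) + 1L, nbins = 256L))
  n <- sum(counts)
  if (sum(counts > 0L) < 2L) {
    return(list(mask = BinaryMask(matrix(0L, nrow(px), ncol(px))),
                threshold = NA_integer_, degenerate = TRUE))
  }
  lv <- 0:255
  w0 <- cumsum(counts)                       # class 0: values <= t
  m0 <- cumsum(counts * lv)
  w1 <- n - w0
  mu <- m0[256]
  # between-class variance for thresholds t = 0..255 (index t + 1)
  valid <- w0 > 0 & w1 > 0
  sigmaB <- rep(-Inf, 256)
  sigmaB[valid] <- (mu * w0[valid] - n * m0[valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  tstar <- which.max(sigmaB) - 1L            # lowest maximizer
  mask <- matrix(0L, nrow(px), ncol(px))
  mask[px > tstar] <- 255L
  list(mask = BinaryMask(mask), threshold = tstar, degenerate = FALSE)
}

#' Skeletonize a binary mask
#'
#' Iterative thinning to idempotence: simple points (pixels whose removal
#' does not change the local 8-connected topology) with at least two
#' foreground neighbours are removed in directional sub-passes until the
#' image stabilizes. The skeleton is a subset of the input foreground,
#' applying the operation twice equals applying it once, and the number of
#' 8-connected components is preserved.
#'
#' @param mask a [BinaryMask-class] (or 0/1, 0/255 or logical matrix).
#' @return A [BinaryMask-class].
#' @export
skeletonize <- function(mask) {
  m <- mask01(mask)
  BinaryMask(cpp_thin(m),
             origin = if (is(mask, "BinaryMask")) mask@origin else c(0L, 0L))
}

#' Binary dilation and erosion
#'
#' One dilation iteration sets a pixel to foreground if any pixel of its
#' 3 x 3 neighbourhood is foreground (maximum filter); erosion is the dual
#' minimum filter. Pixels outside the frame count as background. Iterations
#' compose; zero iterations is the identity.
#'
#' @param mask a [BinaryMask-class] (or 0/1, 0/255 or logical matrix).
#' @param iterations non-negative iteration count.
#' @return A [BinaryMask-class].
#' @export
dilateMask <- function(mask, iterations = 1L) {
  if (iterations < 0) stop("iterations must be >= 0")
  BinaryMask(cpp_dilate(mask01(mask), as.integer(iterations)),
             origin = if (is(mask, "BinaryMask")) mask@origin else c(0L, 0L))
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, iterations = 1L) {
  if (iterations < 0) stop("iterations must be >= 0")
  BinaryMask(cpp_erode(mask01(mask), as.integer(iterations)),
             origin = if (is(mask, "BinaryMask")) mask@origin else c(0L, 0L))
}

#' Wand (flood fill) region selection
#'
#' Flood-fills the connected set of pixels whose value differs from the seed
#' pixel's value by at most `tolerance`. If the seed lands on a bright
#' (vessel-valued, >= 128) pixel, the nearest pixel below 128 within
#' `rescueRadius` (Euclidean; ties broken by row-major scan order) is used
#' instead and a warning is recorded; if none exists the selection fails
#' with a "FAZ seed failure" error (a vessel-covered centre).
#'
#' @param image 8-bit matrix or [Angiogram-class].
#' @param seed 0-based (x, y) seed.
#' @param tolerance intensity tolerance (0 selects exactly-equal pixels).
#' @param rescueRadius seed rescue search radius in pixels.
#' @param connectivity 4 (default) or 8.
#' @return `list(mask = BinaryMask, seedUsed = c(x, y), warnings = character)`.
#' @export
wandRegion <- function(image, seed = c(255L, 255L), tolerance = 0L,
                       rescueRadius = 10L, connectivity = 4L) {
  px <- asPixelMatrix(image)
  H <- nrow(px); W <- ncol(px)
  x <- as.integer(seed[1]); y <- as.integer(seed[2])
  if (x < 0L || x >= W || y < 0L || y >= H) stop("seed outside image")
  warnings <- character()
  if (px[y + 1L, x + 1L] >= 128) {
    # seed landed on a vessel: re-seed on the nearest dark pixel
    r <- as.integer(ceiling(rescueRadius))
    ys <- max(0L, y - r):min(H - 1L, y + r)
    xs <- max(0L, x - r):min(W - 1L, x + r)
    cand <- expand.grid(cy = ys, cx = xs)   # row-major scan order in ties
    cand <- cand[order(cand$cy, cand$cx), ]
    d2 <- (cand$cx - x)^2 + (cand$cy - y)^2
    ok <- d2 <= rescueRadius^2 & px[cbind(cand$cy + 1L, cand$cx + 1L)] < 128
    if (!any(ok))
      stop("FAZ seed failure: no dark pixel within ", rescueRadius,
           " px of the wand seed")
    pick <- which(ok)[which.min(d2[ok])]
    nx <- cand$cx[pick]; ny <- cand$cy[pick]
    warnings <- sprintf(
      "wand seed (%d, %d) on vessel pixel; re-seeded at (%d, %d)", x, y, nx, ny)
    x <- nx; y <- ny
  }
  m <- cpp_flood(matrix(as.numeric(px), H, W), y, x,
                 as.numeric(tolerance), as.integer(connectivity))
  list(mask = BinaryMask(m), seedUsed = c(x, y), warnings = warnings)
}
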