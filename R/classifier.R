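# texture_segmenter: annotation rasterization, training, whole-image
# classification and FAZ region extraction.

bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  xs <- integer(0); ys <- integer(0)
  repeat {
    xs <- c(xs, x0); ys <- c(ys, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(x = xs, y = ys)
}

#' Rasterize line-segment training annotations
#'
#' Bresenham-rasterizes each labelled polyline to pixels. Duplicate pixels
#' are deduplicated keeping the first label; the same pixel carrying two
#' different labels is an error.
#'
#' @param annotations list as returned by [readAnnotations()].
#' @param dim integer (H, W) of the frame the coordinates refer to.
#' @return A data.frame with columns `x`, `y` (0-based) and `label`.
#' @export
rasterizeAnnotations <- function(annotations, dim) {
  H <- dim[1]; W <- dim[2]
  out <- do.call(rbind, lapply(annotations, function(a) {
    pts <- round(a$points)
    if (nrow(pts) < 2L) stop("polyline needs at least 2 vertices")
    if (any(pts[, 1] < 0 | pts[, 1] >= W | pts[, 2] < 0 | pts[, 2] >= H))
      stop("annotation vertex outside the ", H, " x ", W, " frame")
    segs <- do.call(rbind, lapply(seq_len(nrow(pts) - 1L), function(i)
      bresenham(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2])))
    data.frame(x = segs[, 1], y = segs[, 2], label = a$label,
               stringsAsFactors = FALSE)
  }))
  key <- paste(out$x, out$y)
  first <- !duplicated(key)
  firstLabel <- out$label[first][match(key, key[first])]
  conflict <- out$label != firstLabel
  if (any(conflict)) {
    i <- which(conflict)[1]
    stop(sprintf("conflicting labels at pixel (%d, %d)", out$x[i], out$y[i]))
  }
  out[first, , drop = FALSE]
}

#' Train the texture pixel classifier
#'
#' Fits a probability random forest to the feature vectors of the labelled
#' pixels. Training is deterministic given the seed. The resubstitution
#' accuracy on the training pixels is computed as a sanity check: below 0.95
#' a warning is raised (as with randomly shuffled labels).
#'
#' @param stack a [FeatureStack-class] of the training image.
#' @param labeled data.frame with 0-based `x`, `y` and
#'   `label` (`"vascular"`/`"avascular"`), e.g. from
#'   [rasterizeAnnotations()].
#' @param nTrees number of trees.
#' @param seed integer seed for the forest.
#' @param provenance optional list (annotation hash, source image ids) stored
#'   with the model.
#' @return A [PixelClassifierModel-class].
#' @export
trainClassifier <- function(stack, labeled, nTrees = 100L, seed,
                            provenance = list()) {
  stopifnot(is(stack, "FeatureStack"))
  lab <- factor(labeled$label, levels = c("vascular", "avascular"))
  if (anyNA(lab)) stop("labels must be 'vascular' or 'avascular'")
  if (nlevels(droplevels(lab)) < 2L)
    stop("need both vascular and avascular examples")
  H <- stack@dim[1]
  idx <- labeled$y + labeled$x * H + 1L
  X <- stack@features[idx, , drop = FALSE]
  forest <- ranger::ranger(x = X, y = lab, num.trees = as.integer(nTrees),
                           probability = TRUE, seed = as.integer(seed),
                           num.threads = 1L)
  prob <- predict(forest, data = X, num.threads = 1L)$predictions
  predClass <- colnames(prob)[max.col(prob, ties.method = "first")]
  acc <- mean(predClass == as.character(lab))
  if (acc < 0.95)
    warning(sprintf(
      "training accuracy %.3f below the 0.95 sanity bound: check annotations",
      acc))
  new("PixelClassifierModel", forest = forest,
      recipe = list(radii = stack@radii, features = stack@featureNames,
                    nTrees = as.integer(nTrees), seed = as.integer(seed),
                    frameDim = stack@dim),
      classOrder = c("vascular", "avascular"),
      provenance = provenance, trainAccuracy = acc)
}

#' Classify every pixel of an image
#'
#' Applies a trained model uniformly to an image: returns the per-pixel
#' probability of the avascular class and the binary avascular mask at
#' p >= 0.5. Classification never mutates the model. The image (or feature
#' stack) must match the model's recipe: same frame size and same feature
#' set.
#'
#' @param x an 8-bit matrix, [Angiogram-class] (the 512 x 512 analysis
#'   frame), or a precomputed [FeatureStack-class].
#' @param model a [PixelClassifierModel-class].
#' @return `list(probability = matrix, mask = BinaryMask)`.
#' @export
classifyImage <- function(x, model) {
  stopifnot(is(model, "PixelClassifierModel"))
  if (is(x, "FeatureStack")) {
    stack <- x
    if (!identical(as.integer(stack@radii), as.integer(model@recipe$radii)) ||
        !identical(stack@featureNames, model@recipe$features))
      stop("feature recipe mismatch: stack features do not match the model")
    if (!identical(as.integer(stack@dim), as.integer(model@recipe$frameDim)))
      stop("frame mismatch: stack is ", stack@dim[1], " x ", stack@dim[2],
           ", model expects ", model@recipe$frameDim[1], " x ",
           model@recipe$frameDim[2])
  } else {
    px <- asPixelMatrix(x)
    if (!identical(as.integer(dim(px)), as.integer(model@recipe$frameDim)))
      stop("frame mismatch: image is ", nrow(px), " x ", ncol(px),
           ", model expects ", model@recipe$frameDim[1], " x ",
           model@recipe$frameDim[2])
    stack <- computeFeatures(px, radii = model@recipe$radii)
  }
  prob <- predict(model@forest, data = stack@features,
                  num.threads = 1L)$predictions[, "avascular"]
  pm <- matrix(prob, stack@dim[1], stack@dim[2])
  mask <- matrix(0L, stack@dim[1], stack@dim[2])
  mask[pm >= 0.5] <- 255L
  list(probability = pm, mask = BinaryMask(mask))
}

#' Extract the FAZ from an avascular mask
#'
#' Selects the 4-connected avascular component containing the frame centre
#' (or the nearest avascular pixel within `rescueRadius`, recording a
#' warning), fills interior holes smaller than `holeFillPx` pixels (small
#' capillary-dropout speckle), and returns the result as a region.
#'
#' @param mask avascular [BinaryMask-class] (foreground = avascular).
#' @param center 0-based (x, y) expected FAZ centre.
#' @param rescueRadius search radius if the centre pixel is not avascular.
#' @param holeFillPx fill enclosed background components smaller than this.
#' @return A [FazRegion-class] with `method = "ml"`.
#' @export
extractFaz <- function(mask, center = c(255L, 255L), rescueRadius = 10L,
                       holeFillPx = 50L) {
  m <- mask01(mask)
  H <- nrow(m); W <- ncol(m)
  x <- as.integer(center[1]); y <- as.integer(center[2])
  warnings <- character()
  if (m[y + 1L, x + 1L] != 1L) {
    r <- as.integer(ceiling(rescueRadius))
    ys <- max(0L, y - r):min(H - 1L, y + r)
    xs <- max(0L, x - r):min(W - 1L, x + r)
    cand <- expand.grid(cy = ys, cx = xs)
    cand <- cand[order(cand$cy, cand$cx), ]
    d2 <- (cand$cx - x)^2 + (cand$cy - y)^2
    ok <- d2 <= rescueRadius^2 & m[cbind(cand$cy + 1L, cand$cx + 1L)] == 1L
    if (!any(ok))
      stop("FAZ seed failure: no avascular pixel within ", rescueRadius,
           " px of the centre")
    pick <- which(ok)[which.min(d2[ok])]
    warnings <- sprintf(
      "centre (%d, %d) not avascular; re-seeded at (%d, %d)",
      x, y, cand$cx[pick], cand$cy[pick])
    x <- cand$cx[pick]; y <- cand$cy[pick]
  }
  comp <- cpp_flood(matrix(as.numeric(m), H, W), y, x, 0, 4L)
  # fill enclosed holes below the size threshold
  inv <- 1L - comp
  labs <- cpp_label(inv, 4L)
  borderLabs <- unique(c(labs[1, ], labs[H, ], labs[, 1], labs[, W]))
  borderLabs <- borderLabs[borderLabs > 0L]
  if (length(labs) && max(labs) > 0L) {
    sizes <- tabulate(labs[labs > 0L], nbins = max(labs))
    fill <- setdiff(which(sizes < holeFillPx), borderLabs)
    if (length(fill)) comp[labs %in% fill] <- 1L
  }
  FazRegion(BinaryMask(comp), method = "ml", warnings = warnings)
}

#' Save / load a pixel classifier model
#'
#' The file embeds the feature recipe, class order, provenance and the
#' forest itself; loading validates the recipe (a tampered feature list is a
#' recipe-mismatch error) and a save/load round trip reproduces predictions
#' bit-identically.
#'
#' @param model a [PixelClassifierModel-class].
#' @param path destination file.
#' @return `saveModel` returns `path` invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "PixelClassifierModel"))
  saveRDS(list(format = "fazkit-model-v1", recipe = model@recipe,
               classOrder = model@classOrder, provenance = model@provenance,
               trainAccuracy = model@trainAccuracy, forest = model@forest),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "fazkit-model-v1"))
    stop("'", path, "' is not a fazkit model file")
  expected <- featureNamesFor(obj$recipe$radii)
  if (!identical(obj$recipe$features, expected))
    stop("recipe mismatch: model feature list does not match its radii ",
         "(file may be corrupted or tampered with)")
  new("PixelClassifierModel", forest = obj$forest, recipe = obj$recipe,
      classOrder = obj$classOrder, provenance = obj$provenance,
      trainAccuracy = obj$trainAccuracy)
}
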