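# synthetic_octa: en-face OCTA-like angiograms with known FAZ ground truth,
# single images and longitudinal cohorts.

#' Default cohort FAZ-area parameters
#'
#' Visit-mean FAZ area trajectories (mm^2) and cross-sectional between-eye
#' SDs per plexus used as cohort defaults; visit 1 is the preoperative
#' baseline and visits 2-4 the postoperative follow-ups. The SVP trajectory
#' carries the characteristic visit-3/4 shrinkage.
#'
#' @return `fazTrajectoryDefaults()`: a named list of length-4 numeric
#'   vectors; `fazBetweenSdDefaults()`: a named numeric vector.
#' @export
fazTrajectoryDefaults <- function() {
  list(SVP = c(0.49, 0.45, 0.41, 0.41),
       IVP = c(0.15, 0.14, 0.14, 0.17),
       DVP = c(0.41, 0.39, 0.37, 0.38))
}

#' @rdname fazTrajectoryDefaults
#' @export
fazBetweenSdDefaults <- function() c(SVP = 0.25, IVP = 0.11, DVP = 0.21)

# smooth periodic boundary perturbation: low-order cosine harmonics with
# random amplitudes/phases, normalized to max |s| = 1
makeBoundaryPerturbation <- function() {
  ks <- 2:5
  ck <- rnorm(length(ks)) / ks
  ph <- runif(length(ks), 0, 2 * pi)
  f <- function(theta) {
    s <- 0
    for (i in seq_along(ks)) s <- s + ck[i] * cos(ks[i] * theta + ph[i])
    s
  }
  grid <- seq(0, 2 * pi, length.out = 2048)
  m <- max(abs(f(grid)))
  if (m < 1e-12) return(function(theta) 0 * theta)
  function(theta) f(theta) / m
}

drawWalk <- function(V, xs, ys, width, intensity) {
  H <- nrow(V); W <- ncol(V)
  px <- round(xs); py <- round(ys)
  if (width >= 2L) {
    offs <- if (width == 2L) cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
            else as.matrix(expand.grid(-1:1, -1:1))
    k <- nrow(offs); n <- length(px)
    px <- rep(px, each = k) + rep(offs[, 1], times = n)
    py <- rep(py, each = k) + rep(offs[, 2], times = n)
  }
  ok <- px >= 0 & px < W & py >= 0 & py < H
  idx <- unique(py[ok] + px[ok] * H + 1L)
  V[idx] <- pmax(V[idx], intensity)
  V
}

#' Simulate an en-face OCTA angiogram with known FAZ ground truth
#'
#' Builds a source-frame image whose central avascular zone is an irregular
#' star-convex polygon of prescribed area, surrounded by inward-biased
#' vessel walks that terminate at the FAZ boundary and a background
#' capillary mesh, then applies Gaussian blur, multiplicative lognormal
#' speckle and 8-bit quantization. The ground truth is the vessel-free
#' polygon interior, returned as a region in 512 x 512 analysis-frame
#' coordinates. Deterministic given the seed.
#'
#' @param fazAreaMm2 target FAZ area in mm^2 (converted to pixels with the
#'   magnification-corrected scale for `alMm`).
#' @param alMm axial length in mm.
#' @param plexus plexus label stored in the metadata.
#' @param vesselDensity background capillary mesh density in (0, 1].
#' @param boundaryIrregularity radial perturbation amplitude as a fraction
#'   of the mean radius (0 = circle).
#' @param noiseSigma lognormal speckle sigma (0 = none).
#' @param blurSigma Gaussian blur sigma in pixels (0 = none).
#' @param seed integer; all randomness flows from it.
#' @param imageSize source frame side (the 512 x 512 analysis crop at offset
#'   127 must fit).
#' @param scaling a [scalingConfig()].
#' @param subjectId,eye,visit,qualityIndex metadata fields.
#' @return `list(angiogram = Angiogram (source frame, with metadata),
#'   truth = FazRegion ("truth", crop coordinates), scaleMmPerPx,
#'   targetPx)`.
#' @export
simulateAngiogram <- function(fazAreaMm2 = 0.49, alMm = 23.95,
                              plexus = "SVP", vesselDensity = 0.4,
                              boundaryIrregularity = 0.15, noiseSigma = 0.3,
                              blurSigma = 0.8, seed = 1L, imageSize = 768L,
                              scaling = scalingConfig(), subjectId = "SYN",
                              eye = "OD", visit = 1L, qualityIndex = 30L) {
  if (fazAreaMm2 <= 0) stop("fazAreaMm2 must be positive")
  if (vesselDensity <= 0 || vesselDensity > 1)
    stop("vesselDensity must be in (0, 1]")
  if (imageSize < 639L) stop("imageSize must fit the 512 x 512 crop (>= 639)")
  scale <- correctedScale(alMm, scaling)
  targetPx <- fazAreaMm2 / scale^2
  withSeed(seed, {
    sFun <- makeBoundaryPerturbation()
    a <- min(boundaryIrregularity, 0.8)
    grid <- seq(0, 2 * pi, length.out = 2049)[-2049]
    I <- mean((1 + a * sFun(grid))^2) * 2 * pi
    r0 <- sqrt(2 * targetPx / I)
    rOf <- function(theta) r0 * (1 + a * sFun(theta))
    rMax <- max(rOf(grid))
    if (rMax > 245) stop("FAZ too large for the 512 x 512 analysis frame")
    cx <- 127 + 255.5; cy <- 127 + 255.5   # source-frame FAZ centre
    H <- as.integer(imageSize); W <- H
    V <- matrix(0, H, W)

    # perifoveal spokes: inward-biased walks terminating at the boundary
    nSpokes <- max(36L, as.integer(round(2 * pi * r0 / 5)))
    for (i in seq_len(nSpokes)) {
      th0 <- 2 * pi * (i - 1) / nSpokes + rnorm(1, 0, pi / (2 * nSpokes))
      rStart <- min(rOf(th0) * runif(1, 1.25, 2.2), imageSize / 2 - 5)
      nst <- as.integer(ceiling(rStart / 0.5))
      th <- th0 + cumsum(rnorm(nst, 0, 0.015))
      rho <- rStart - cumsum(runif(nst, 0.5, 1))
      hit <- which(rho <= rOf(th))
      if (length(hit)) {
        keep <- seq_len(hit[1])
        th <- th[keep]; rho <- rho[keep]
      }
      V <- drawWalk(V, cx + rho * cos(th), cy + rho * sin(th),
                    width = sample(2:3, 1), intensity = runif(1, 150, 255))
    }

    # background capillary mesh outside the FAZ. vesselDensity is the target
    # vessel-area fraction of the background; a walk of ~80 unit steps at
    # width 2-3 paints ~140 distinct pixels net of overlap, which calibrates
    # the walk count. Walks are generated in one vectorized batch.
    nMesh <- as.integer(round(vesselDensity * (H * W - pi * r0^2) / 140))
    if (nMesh > 0L) {
      xs0 <- numeric(0); ys0 <- numeric(0)
      while (length(xs0) < nMesh) {      # rejection-sample outside the FAZ
        m <- 2L * (nMesh - length(xs0)) + 10L
        tx <- runif(m, 0, W - 1); ty <- runif(m, 0, H - 1)
        th <- atan2(ty - cy, tx - cx)
        ok <- sqrt((tx - cx)^2 + (ty - cy)^2) > rOf(th) + 6
        xs0 <- c(xs0, tx[ok]); ys0 <- c(ys0, ty[ok])
      }
      xs0 <- xs0[seq_len(nMesh)]; ys0 <- ys0[seq_len(nMesh)]
      L <- as.integer(round(runif(nMesh, 40, 120)))
      id <- rep.int(seq_len(nMesh), L)
      ends <- cumsum(L)
      gcum <- function(v) {              # cumulative sums within each walk
        cs <- cumsum(v)
        cs - c(0, cs[ends[-nMesh]])[id]
      }
      eps <- rnorm(sum(L), 0, 0.25)
      hd <- runif(nMesh, 0, 2 * pi)[id] + gcum(eps)
      px <- round(xs0[id] + gcum(cos(hd)))
      py <- round(ys0[id] + gcum(sin(hd)))
      wv <- sample(c(2L, 2L, 3L), nMesh, replace = TRUE)[id]
      val <- runif(nMesh, 150, 255)[id]
      allPx <- integer(0); allPy <- integer(0); allV <- numeric(0)
      for (w in c(2L, 3L)) {
        sel <- wv == w
        if (!any(sel)) next
        offs <- if (w == 2L) cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
                else as.matrix(expand.grid(-1:1, -1:1))
        k <- nrow(offs); n <- sum(sel)
        allPx <- c(allPx, rep(px[sel], each = k) + rep(offs[, 1], times = n))
        allPy <- c(allPy, rep(py[sel], each = k) + rep(offs[, 2], times = n))
        allV <- c(allV, rep(val[sel], each = k))
      }
      ok <- allPx >= 0 & allPx < W & allPy >= 0 & allPy < H
      idx <- allPy[ok] + allPx[ok] * H + 1
      v <- allV[ok]
      ord <- order(v)                    # ascending: brightest wins below
      Vm <- matrix(0, H, W)
      Vm[idx[ord]] <- v[ord]
      V <- pmax(V, Vm)
    }

    # enforce a vessel-free interior: the truth region is exactly the set of
    # pixels at or inside the boundary polygon
    xg <- matrix(rep(0:(W - 1), each = H), H, W)
    yg <- matrix(rep(0:(H - 1), times = W), H, W)
    rho <- sqrt((xg - cx)^2 + (yg - cy)^2)
    theta <- atan2(yg - cy, xg - cx)
    inside <- rho <= rOf(theta)
    V[inside] <- 0

    if (blurSigma > 0) V <- cpp_gauss_blur(V, blurSigma)
    if (noiseSigma > 0)
      V <- V * rlnorm(length(V), meanlog = -noiseSigma^2 / 2,
                      sdlog = noiseSigma)
    V <- roundHalfUp(V)
    V[V > 255] <- 255
    V[V < 0] <- 0
    storage.mode(V) <- "integer"

    # ground truth in crop coordinates
    cropIdx <- 128:639
    truthMask <- matrix(0L, 512L, 512L)
    truthMask[inside[cropIdx, cropIdx]] <- 255L
    meta <- ScanMetadata(subjectId, eye, visit, plexus, alMm, qualityIndex)
    truth <- FazRegion(BinaryMask(truthMask), method = "truth",
                       areaMm2 = sum(truthMask == 255L) * scale^2)
    list(angiogram = Angiogram(V, metadata = meta), truth = truth,
         scaleMmPerPx = scale, targetPx = targetPx, boundaryRadius = rOf)
  })
}

#' Simulate a longitudinal cohort
#'
#' Draws an axial length per eye (truncated normal), a per-plexus random eye
#' effect, and per-visit true FAZ areas around the default visit-mean
#' trajectories; optionally renders and writes every scan as a TIFF with a
#' metadata sidecar and a ground-truth area table. One record per
#' eye x visit x plexus is always returned, so the scan count is
#' `nEyes * 4 * length(plexuses)`.
#'
#' @param nEyes number of eyes.
#' @param seed integer master seed; per-scan seeds derive from it.
#' @param plexuses which plexuses to simulate.
#' @param trajectories named list of visit-mean areas (mm^2) per plexus.
#' @param betweenSd named vector of cross-sectional SDs per plexus; the
#'   between-eye effect SD is `sqrt(betweenSd^2 - withinSd^2)`.
#' @param withinSd within-eye visit-to-visit SD in mm^2.
#' @param alMean,alSd,alRange axial-length distribution (mm), truncated.
#' @param qualityRange inclusive range of simulated quality indices.
#' @param imageDir if non-NULL, render every scan there
#'   (`<subject>_<eye>_v<visit>_<plexus>.tif`) plus `meta.csv` and
#'   `truth.csv`.
#' @param ... further arguments passed to [simulateAngiogram()]
#'   (vesselDensity, noiseSigma, ...).
#' @return `list(metadata = data.frame (sidecar columns), truth = data.frame
#'   with true_area_mm2, dir = imageDir or NULL)`.
#' @export
simulateCohort <- function(nEyes = 59L, seed = 1L,
                           plexuses = c("SVP", "IVP", "DVP"),
                           trajectories = fazTrajectoryDefaults(),
                           betweenSd = fazBetweenSdDefaults(),
                           withinSd = 0.05, alMean = 23.79, alSd = 1.7,
                           alRange = c(21, 26), qualityRange = c(18L, 40L),
                           imageDir = NULL, ...) {
  stopifnot(nEyes >= 1L, all(plexuses %in% c("SVP", "IVP", "DVP")))
  visits <- 1:4
  withSeed(seed, {
    al <- numeric(nEyes)
    for (i in seq_len(nEyes)) {
      repeat {
        v <- rnorm(1, alMean, alSd)
        if (v > alRange[1] && v < alRange[2]) break
      }
      al[i] <- v
    }
    subject <- sprintf("S%03d", seq_len(nEyes))
    eyeLat <- rep(c("OD", "OS"), length.out = nEyes)
    rows <- list()
    for (i in seq_len(nEyes)) {
      for (pl in plexuses) {
        eyeSd <- sqrt(max(betweenSd[[pl]]^2 - withinSd^2, 0))
        eff <- rnorm(1, 0, eyeSd)
        areas <- trajectories[[pl]] + eff + rnorm(length(visits), 0, withinSd)
        for (tries in 1:1000) {
          bad <- areas <= 0.02
          if (!any(bad)) break
          areas[bad] <- trajectories[[pl]][bad] + eff +
            rnorm(sum(bad), 0, withinSd)
        }
        areas <- pmax(areas, 0.021)
        for (v in visits) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = subject[i], eye = eyeLat[i], visit = v, plexus = pl,
            axial_length_mm = al[i],
            quality_index = sample(qualityRange[1]:qualityRange[2], 1),
            true_area_mm2 = areas[v], stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    tab$file <- sprintf("%s_%s_v%d_%s.tif", tab$subject_id, tab$eye,
                        tab$visit, tab$plexus)
    scanSeeds <- sample.int(.Machine$integer.max, nrow(tab))
    tab$scan_seed <- scanSeeds
    if (!is.null(imageDir)) {
      dir.create(imageDir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(nrow(tab))) {
        sim <- simulateAngiogram(
          fazAreaMm2 = tab$true_area_mm2[i], alMm = tab$axial_length_mm[i],
          plexus = tab$plexus[i], seed = scanSeeds[i],
          subjectId = tab$subject_id[i], eye = tab$eye[i],
          visit = tab$visit[i], qualityIndex = tab$quality_index[i], ...)
        tiff::writeTIFF(sim$angiogram@pixels / 255,
                        file.path(imageDir, tab$file[i]),
                        bits.per.sample = 8L)
      }
      meta <- tab[c("file", "subject_id", "eye", "visit", "plexus",
                    "axial_length_mm", "quality_index")]
      write.csv(meta, file.path(imageDir, "meta.csv"), row.names = FALSE)
      write.csv(tab[c("subject_id", "eye", "visit", "plexus",
                      "true_area_mm2")],
                file.path(imageDir, "truth.csv"), row.names = FALSE)
    }
    meta <- tab[c("file", "subject_id", "eye", "visit", "plexus",
                  "axial_length_mm", "quality_index")]
    truth <- tab[c("subject_id", "eye", "visit", "plexus", "true_area_mm2",
                   "axial_length_mm", "file", "scan_seed")]
    list(metadata = meta, truth = truth, dir = imageDir)
  })
}

#' Training annotations for a synthetic angiogram
#'
#' Builds the six line annotations (three avascular, three vascular) used to
#' train the pixel classifier from a single synthetic "patient" image,
#' emulating interactive training on clear vascular/avascular patterns with
#' the correct boundaries: an avascular chord plus two arcs drawn just
#' inside the ground-truth FAZ boundary, and two arcs just outside it plus a
#' line across the capillary mesh. Coordinates are in the 512 x 512 analysis
#' frame.
#'
#' @param truth the ground-truth [FazRegion-class] of the training image.
#' @param boundaryRadius optional function theta -> radius (px) of the true
#'   FAZ boundary (returned by [simulateAngiogram()]); without it a circular
#'   boundary of equal area is assumed.
#' @param imageId identifier stored with the annotations.
#' @return An annotation list as returned by [readAnnotations()].
#' @export
syntheticAnnotations <- function(truth, boundaryRadius = NULL,
                                 imageId = "training") {
  r0 <- sqrt(pixelCount(truth) / pi)
  rOf <- if (is.null(boundaryRadius)) function(theta) rep(r0, length(theta))
         else boundaryRadius
  cx <- 255.5
  arc <- function(frac, th0, th1) {
    th <- seq(th0, th1, length.out = 16)
    rr <- pmin(frac * rOf(th), 250)
    cbind(cx + rr * cos(th), cx + rr * sin(th))
  }
  ann <- function(label, points)
    list(imageId = imageId, label = label, points = points)
  list(
    ann("avascular", arc(0.85, 0, pi)),
    ann("avascular", arc(0.85, pi, 2 * pi)),
    ann("avascular", cbind(c(cx - 0.5 * r0, cx + 0.5 * r0), c(cx, cx))),
    ann("vascular", arc(1.12, 0, pi)),
    ann("vascular", arc(1.12, pi, 2 * pi)),
    ann("vascular", cbind(c(30, 200, 460), c(40, 40, 300))))
}
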