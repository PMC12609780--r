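test_that("to8bit handles identity, scaling and degenerate inputs", {
  px <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  expect_identical(to8bit(px), matrix(as.integer(px), 10, 10))
  # 16-bit: occupied-range min-max scaling, round half up
  m16 <- matrix(c(0, 32768, 65535), 1, 3)
  expect_identical(as.vector(to8bit(m16, bitDepth = 16L)), c(0L, 128L, 255L))
  # constant 16-bit maps to zero
  expect_true(all(to8bit(matrix(700, 4, 4), bitDepth = 16L) == 0L))
  # colour -> luminance
  arr <- array(0, c(2, 2, 3)); arr[, , 1] <- 255
  expect_true(all(to8bit(arr) == 76L))   # round(0.299 * 255)
  expect_error(to8bit(matrix(numeric(0), 0, 0)), "empty")
})

test_that("centerCrop extracts the analysis frame with exact offsets", {
  src <- matrix(seq_len(768 * 768) %% 251, 768, 768)
  crop <- centerCrop(src)
  expect_equal(dim(crop), c(512, 512))
  expect_equal(crop[1, 1], src[128, 128])
  expect_equal(crop[512, 512], src[639, 639])
  expect_silent(centerCrop(matrix(0, 639, 639)))
  expect_error(centerCrop(matrix(0, 512, 512)), "639")
})

test_that("resizeBilinear preserves constants, interpolates monotonically, averages", {
  cst <- resizeBilinear(matrix(128, 512, 512), 270, 270)
  expect_true(all(cst == 128L))
  up <- resizeBilinear(matrix(c(0, 0, 255, 255), 2, 2), 4, 4)
  expect_true(all(up[, 1] == 0) && all(up[, 4] == 255))
  expect_true(all(up[, 2:3] > 0 & up[, 2:3] < 255))
  # 4x4 checkerboard downscaled with averaging: every pixel ~ 128
  cb <- 255L * outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
  dn <- resizeBilinear(cb, 2, 2, averageOnDownscale = TRUE)
  expect_true(all(abs(dn - 128) <= 1))
  expect_error(resizeBilinear(cb, 0, 2), "positive")
})

test_that("otsuThreshold matches exhaustive between-class-variance search", {
  # perfectly bimodal image
  bi <- matrix(rep(c(0L, 255L), each = 32), 8, 8)
  ot <- otsuThreshold(bi)
  expect_identical(pixels(ot$mask) == 255L, bi == 255L)
  # constant image is degenerate
  dg <- otsuThreshold(matrix(7L, 5, 5))
  expect_true(dg$degenerate)
  expect_true(all(pixels(dg$mask) == 0L))
  # randomized oracle comparison
  set.seed(421)
  for (i in 1:30) {
    px <- matrix(sample(0:255, 32 * 32, replace = TRUE,
                        prob = runif(256)^2), 32, 32)
    expect_identical(otsuThreshold(px)$threshold, oracleOtsu(px))
  }
})

test_that("dilate/erode agree bit-identically with the neighbourhood-scan oracle", {
  set.seed(77)
  for (i in 1:25) {
    m <- randMask()
    it <- sample(0:3, 1)
    expect_identical(mask01(dilateMask(m, it)),
                     oracleMorph(m, oracleDilate1, it))
    expect_identical(mask01(erodeMask(m, it)),
                     oracleMorph(m, oracleErode1, it))
  }
  expect_error(dilateMask(randMask(), -1), ">= 0")
})

test_that("morphology monotonicity and closing identity", {
  set.seed(78)
  for (i in 1:10) {
    m <- randMask()
    d <- mask01(dilateMask(m, 1))
    e <- mask01(erodeMask(m, 1))
    expect_true(all(d >= m))   # dilation never removes foreground
    expect_true(all(e <= m))   # erosion never adds foreground
  }
  # closing of a convex region away from borders restores it
  disc <- matrix(0L, 40, 40)
  for (i in 1:40) for (j in 1:40)
    if ((i - 20.5)^2 + (j - 20.5)^2 <= 100) disc[i, j] <- 1L
  k <- 3L
  closed <- mask01(erodeMask(dilateMask(disc, k), k))
  expect_identical(closed, disc)
})

test_that("skeletonize: subset, idempotence, thin lines unchanged, rectangle", {
  # empty and already-thin inputs
  expect_true(all(mask01(skeletonize(matrix(0L, 8, 8))) == 0L))
  line <- matrix(0L, 9, 9); line[5, 2:8] <- 1L
  expect_identical(mask01(skeletonize(line)), line)
  # filled rectangle thins to a single thin component
  rect <- matrix(0L, 11, 26); rect[4:8, 4:23] <- 1L
  sk <- mask01(skeletonize(rect))
  expect_true(all(sk <= rect))
  expect_equal(oracleComponents8(sk), 1L)
  expect_identical(mask01(skeletonize(sk)), sk)   # idempotent
  # thinness: away from junctions, skeleton pixels have <= 2 neighbours
  H <- nrow(sk); W <- ncol(sk)
  counts <- sapply(which(sk == 1L), function(ix) {
    i <- (ix - 1) %% H + 1; j <- (ix - 1) %/% H + 1
    s <- 0
    for (di in -1:1) for (dj in -1:1)
      if (!(di == 0 && dj == 0) && i + di >= 1 && i + di <= H &&
          j + dj >= 1 && j + dj <= W && sk[i + di, j + dj] == 1L) s <- s + 1
    s
  })
  expect_true(mean(counts <= 2) > 0.9)
})

test_that("wandRegion selects, rescues and fails as specified", {
  # uniform image: whole frame selected
  w <- wandRegion(matrix(0L, 20, 20), seed = c(5L, 5L))
  expect_equal(sum(pixels(w$mask) == 255L), 400L)
  # black disc on white, tolerance 0: exact rasterized pixel count
  img <- matrix(255L, 512, 512)
  inDisc <- outer(0:511, 0:511, function(y, x) (x - 255)^2 + (y - 255)^2 <= 40^2)
  img[inDisc] <- 0L
  w2 <- wandRegion(img, seed = c(255L, 255L), tolerance = 0L)
  expect_equal(sum(pixels(w2$mask) == 255L), sum(inDisc))
  expect_length(w2$warnings, 0)
  # seed on a vessel pixel: nearest dark pixel rescues with a warning
  img3 <- matrix(255L, 30, 30); img3[16, 19] <- 0L   # 3 px right of (15,15)
  w3 <- wandRegion(img3, seed = c(15L, 15L), rescueRadius = 10L)
  expect_match(w3$warnings, "re-seeded")
  expect_equal(sum(pixels(w3$mask) == 255L), 1L)
  # no dark pixel in range: seed failure
  expect_error(wandRegion(matrix(255L, 30, 30), seed = c(15L, 15L)),
               "FAZ seed failure")
})

test_that("full pipeline is deterministic and errors on degenerate input", {
  sim <- trainingSim()
  r1 <- runScriptPipeline(sim$angiogram)
  r2 <- runScriptPipeline(sim$angiogram)
  expect_identical(pixels(regionMask(r1)), pixels(regionMask(r2)))
  expect_equal(segMethod(r1), "script")
  expect_equal(pixelCount(r1), sum(pixels(regionMask(r1)) == 255L))
  expect_error(runScriptPipeline(matrix(0L, 768, 768)), "FAZ undefined")
})

test_that("pipeline recovers a clean disc up to the net morphological margin", {
  # noise-free vessel-free disc: expected recovery is the disc eroded by the
  # net dilate-erode margin at the working scale, within perimeter x 5 px
  sim <- simulateAngiogram(fazAreaMm2 = 0.49, boundaryIrregularity = 0,
                           noiseSigma = 0, blurSigma = 0, seed = 31L)
  reg <- runScriptPipeline(sim$angiogram)
  r <- sqrt(pixelCount(sim$truth) / pi)
  margin <- (8 - 4) * 512 / 270
  expected <- pi * (r - margin)^2
  tol <- 2 * pi * r * 5
  expect_lt(abs(pixelCount(reg) - expected), tol)
})

test_that("stage intermediates are retrievable", {
  sim <- trainingSim()
  out <- runScriptPipeline(sim$angiogram, keepIntermediates = TRUE)
  expect_named(out, c("region", "intermediates"))
  expect_equal(dim(out$intermediates$`03_downscaled`), c(270, 270))
  expect_s4_class(out$intermediates$`04_binary`, "BinaryMask")
  expect_equal(dim(out$intermediates$`08_upscaled`), c(512, 512))
})
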