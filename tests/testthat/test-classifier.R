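test_that("Bresenham rasterization: horizontal, diagonal, conflicts", {
  h <- rasterizeAnnotations(list(list(imageId = "t", label = "vascular",
                                      points = cbind(c(2, 11), c(5, 5)))),
                            dim = c(64, 64))
  expect_equal(nrow(h), 10)
  expect_true(all(h$y == 5))
  d <- rasterizeAnnotations(list(list(imageId = "t", label = "avascular",
                                      points = cbind(c(0, 3), c(0, 3)))),
                            dim = c(64, 64))
  expect_equal(d$x, 0:3)
  expect_equal(d$y, 0:3)
  # crossing lines with different labels error at the crossing pixel
  cross <- list(
    list(imageId = "t", label = "vascular", points = cbind(c(0, 10), c(5, 5))),
    list(imageId = "t", label = "avascular", points = cbind(c(5, 5), c(0, 10))))
  expect_error(rasterizeAnnotations(cross, c(64, 64)), "conflicting labels")
  # out-of-bounds vertex
  expect_error(rasterizeAnnotations(
    list(list(imageId = "t", label = "vascular",
              points = cbind(c(0, 70), c(0, 0)))), c(64, 64)), "outside")
})

test_that("training on separable toy features reaches perfect accuracy", {
  set.seed(5)
  px <- matrix(0L, 20, 20)
  px[, 11:20] <- 230L   # right half bright
  st <- computeFeatures(px, radii = 1)
  lab <- data.frame(x = c(rep(2L, 10), rep(15L, 10)),
                    y = rep(0:9, 2),
                    label = rep(c("avascular", "vascular"), each = 10))
  m <- trainClassifier(st, lab, nTrees = 50, seed = 3)
  expect_equal(m@trainAccuracy, 1.0)
  expect_error(trainClassifier(st, lab[lab$label == "vascular", ], seed = 3),
               "both vascular and avascular")
})

test_that("shuffled labels trip the training-accuracy sanity bound", {
  sim <- trainingSim()
  st <- trainingStack()
  lab <- rasterizeAnnotations(
    syntheticAnnotations(sim$truth, sim$boundaryRadius), c(512, 512))
  set.seed(8)
  lab$label <- sample(lab$label)
  expect_warning(trainClassifier(st, lab, seed = 3), "sanity bound")
})

test_that("training and classification are deterministic given the seed", {
  px <- matrix(0L, 20, 20); px[, 11:20] <- 230L
  st <- computeFeatures(px, radii = 1)
  lab <- data.frame(x = c(rep(2L, 10), rep(15L, 10)), y = rep(0:9, 2),
                    label = rep(c("avascular", "vascular"), each = 10))
  m1 <- trainClassifier(st, lab, seed = 42)
  m2 <- trainClassifier(st, lab, seed = 42)
  p1 <- classifyImage(st, m1)
  p2 <- classifyImage(st, m2)
  expect_identical(p1$probability, p2$probability)
})

test_that("classification is a pure function of the model", {
  m <- trainedModel()
  before <- fazkit:::objectHash(m@recipe)
  fb <- m@forest$forest$split.values
  cls <- classifyImage(trainingStack(), m)
  expect_identical(fazkit:::objectHash(m@recipe), before)
  expect_identical(m@forest$forest$split.values, fb)
  expect_true(all(cls$probability >= 0 & cls$probability <= 1))
  # annotated pixels are reproduced (model invariant)
  sim <- trainingSim()
  lab <- rasterizeAnnotations(
    syntheticAnnotations(sim$truth, sim$boundaryRadius), c(512, 512))
  pred <- cls$probability[cbind(lab$y + 1L, lab$x + 1L)] >= 0.5
  truth <- lab$label == "avascular"
  expect_gte(mean(pred == truth), 0.95)
})

test_that("model save/load round trip preserves predictions; tampering is caught", {
  d <- withr::local_tempdir()
  m <- trainedModel()
  p <- file.path(d, "faz.model")
  saveModel(m, p)
  m2 <- loadModel(p)
  px <- matrix(0L, 20, 20); px[, 11:20] <- 230L
  st <- computeFeatures(pixels(centerCrop(trainingSim()$angiogram)),
                        radii = m@recipe$radii)
  expect_identical(classifyImage(st, m)$probability,
                   classifyImage(st, m2)$probability)
  # tampered feature list
  obj <- readRDS(p)
  obj$recipe$features <- c(obj$recipe$features[-2], "bogus")
  saveRDS(obj, p)
  expect_error(loadModel(p), "recipe mismatch")
  # stack with different radii is refused
  st3 <- computeFeatures(matrix(0L, 512, 512), radii = c(1, 2))
  expect_error(classifyImage(st3, m), "recipe mismatch")
  # frame mismatch
  expect_error(classifyImage(matrix(0L, 100, 100), m), "frame mismatch")
})

test_that("extractFaz selects the centre component, rescues, and fills holes", {
  m <- matrix(0L, 512, 512)
  inDisc <- outer(0:511, 0:511, function(y, x) (x - 255)^2 + (y - 255)^2 <= 50^2)
  m[inDisc] <- 1L
  fz <- extractFaz(BinaryMask(m))
  expect_equal(pixelCount(fz), sum(inDisc))
  expect_equal(segMethod(fz), "ml")
  # interior hole of 20 px is filled and counted
  m2 <- m
  m2[250:253, 250:254] <- 0L   # 20-px hole
  fz2 <- extractFaz(BinaryMask(m2))
  expect_equal(pixelCount(fz2), sum(inDisc))
  # a hole at the threshold size is kept
  m3 <- m
  m3[240:249, 250:254] <- 0L   # 50-px hole
  fz3 <- extractFaz(BinaryMask(m3))
  expect_equal(pixelCount(fz3), sum(inDisc) - 50L)
  # centre on vessel: rescue with warning recorded
  m4 <- m
  m4[254:258, 254:258] <- 0L   # carve out the centre
  fz4 <- extractFaz(BinaryMask(m4))
  expect_match(fz4@warnings, "re-seeded")
  # no avascular pixel near the centre
  expect_error(extractFaz(BinaryMask(matrix(0L, 512, 512))),
               "FAZ seed failure")
})
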