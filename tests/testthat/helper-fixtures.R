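# Shared fixtures, built once per test run. The trained classifier emulates
# the single-patient training regime: one synthetic training image, three
# avascular and three vascular line annotations.

.fixtures <- new.env()

trainingSim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulateAngiogram(fazAreaMm2 = 0.49, seed = 7L)
  .fixtures$sim
}

trainingStack <- function() {
  if (is.null(.fixtures$stack)) {
    sim <- trainingSim()
    crop <- centerCrop(pixels(sim$angiogram))
    .fixtures$stack <- computeFeatures(crop)
  }
  .fixtures$stack
}

trainedModel <- function() {
  if (is.null(.fixtures$model)) {
    sim <- trainingSim()
    lab <- rasterizeAnnotations(
      syntheticAnnotations(sim$truth, sim$boundaryRadius),
      dim(pixels(regionMask(sim$truth))))
    .fixtures$model <- trainClassifier(trainingStack(), lab, seed = 11L)
  }
  .fixtures$model
}

# long-format measurement table for the statistics module: n subject-eyes,
# per-visit means `eff`, between-eye sd `sb`, within-eye sd `sw`
simulateAreaTable <- function(n, eff, sb = 0.2, sw = 0.05,
                              plexus = "SVP", method = "script") {
  k <- length(eff)
  do.call(rbind, lapply(seq_len(n), function(i) {
    e <- rnorm(1, 0, sb)
    data.frame(subject_id = sprintf("S%03d", i), eye = "OD", visit = 1:k,
               plexus = plexus, method = method, pixel_count = 1L,
               area_mm2 = pmax(eff + e + rnorm(k, 0, sw), 1e-4),
               stringsAsFactors = FALSE)
  }))
}
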