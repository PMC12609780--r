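test_that("full study: quality filter, both methods, reports, fault isolation", {
  d <- withr::local_tempdir()
  imgDir <- file.path(d, "scans")
  co <- simulateCohort(nEyes = 2, seed = 51, plexuses = "SVP",
                       imageDir = imgDir)
  meta <- co$metadata
  # one corrupt image and one low-quality scan appended
  writeLines("this is not a TIFF", file.path(imgDir, "corrupt.tif"))
  meta <- rbind(meta,
                data.frame(file = "corrupt.tif", subject_id = "S099",
                           eye = "OD", visit = 1, plexus = "SVP",
                           axial_length_mm = 23.9, quality_index = 30),
                data.frame(file = "lowq.tif", subject_id = "S098",
                           eye = "OD", visit = 1, plexus = "SVP",
                           axial_length_mm = 23.9, quality_index = 12))
  metaCsv <- file.path(d, "meta.csv")
  write.csv(meta, metaCsv, row.names = FALSE)
  modelPath <- file.path(d, "faz.model")
  saveModel(trainedModel(), modelPath)

  out <- runFullStudy(imgDir, metaCsv, modelPath, file.path(d, "out"))
  # 8 valid scans x 2 methods; the corrupt one failed; the low-quality one
  # was excluded before reading
  expect_equal(nrow(out$measurements), 16)
  expect_named(out$failures, "corrupt.tif")
  expect_equal(out$excluded$file, "lowq.tif")
  expect_setequal(unique(out$measurements$method), c("script", "ml"))
  expect_true(all(out$measurements$area_mm2 > 0))
  # areas used the per-eye axial length
  one <- out$measurements[1, ]
  al <- meta$axial_length_mm[meta$file ==
         sprintf("%s_%s_v%d_%s.tif", one$subject_id, one$eye, one$visit,
                 one$plexus)]
  expect_equal(one$area_mm2, pixelsToAreaMm2(one$pixel_count, al))
  # reports and provenance written
  expect_true(file.exists(file.path(d, "out", "measurements.csv")))
  expect_true(file.exists(file.path(d, "out", "agreement_SVP.json")))
  expect_true(file.exists(file.path(d, "out", "longitudinal_SVP_script.json")))
  info <- jsonlite::fromJSON(file.path(d, "out", "run_info.json"))
  expect_equal(info$n_failed, 1)
  expect_match(info$config_hash, "^[0-9a-f]{32}$")
  agr <- out$agreement$SVP
  expect_true(is.numeric(agr$r) && abs(agr$r) <= 1)
  long <- out$longitudinal$SVP_script
  expect_equal(nrow(long$pairwise), 6)

  expect_error(runFullStudy(file.path(d, "missing"), metaCsv, modelPath,
                            file.path(d, "out2")), "no scans")
})

test_that("command-line interface drives the workflow", {
  d <- withr::local_tempdir()
  # flag parser
  pa <- fazkit:::parseArgs(c("--image", "x.tif", "--keep", "--seed", "7"))
  expect_equal(pa$flags$image, "x.tif")
  expect_true(pa$flags$keep)
  expect_equal(pa$flags$seed, "7")
  # script-seg on one rendered scan
  sim <- simulateAngiogram(seed = 61)
  img <- file.path(d, "scan.tif")
  tiff::writeTIFF(pixels(sim$angiogram) / 255, img, bits.per.sample = 8L)
  mask <- file.path(d, "mask.tif")
  outCsv <- file.path(d, "meas.csv")
  reg <- fazkitMain(c("script-seg", "--image", img, "--al", "23.95",
                      "--out-mask", mask, "--out-csv", outCsv))
  expect_s4_class(reg, "FazRegion")
  expect_true(file.exists(mask))
  expect_equal(readMeasurements(outCsv)$pixel_count, pixelCount(reg))
  # agreement subcommand round trip
  s <- simulateAreaTable(6, c(0.5, 0.45, 0.42, 0.41), method = "script")
  m <- s; m$method <- "ml"; m$area_mm2 <- s$area_mm2 + rnorm(nrow(s), 0, 0.01)
  cs <- file.path(d, "table.csv")
  writeMeasurements(rbind(s, m), cs)
  rp <- file.path(d, "agree.json")
  fazkitMain(c("agree", "--csv", cs, "--plexus", "SVP", "--out", rp))
  expect_true(file.exists(rp))
  expect_error(fazkitMain(c("script-seg")), "--image")
})
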