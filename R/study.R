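# cli/run-study orchestration: quality filter -> both segmenters on every
# kept scan -> magnification-corrected areas -> agreement and longitudinal
# reports, with per-scan failure isolation.

#' Run the full two-method FAZ study over an image directory
#'
#' Reads the metadata sidecar, drops scans failing the quality filter, runs
#' both segmenters (the morphological script pipeline and the trained pixel
#' classifier) on every kept scan, converts pixel counts to mm^2 with the
#' per-subject axial length, and emits the long-format measurement table,
#' one agreement report per plexus (pooled over visits) and one longitudinal
#' report per plexus x method. Per-scan failures are logged and excluded,
#' not fatal; the failure summary lists them.
#'
#' @param imageDir directory of angiogram TIFF/PNG files.
#' @param metaCsv metadata sidecar CSV (see [readMetadataCsv()]).
#' @param modelPath a trained classifier file from [saveModel()].
#' @param outDir output directory (created); receives `measurements.csv`,
#'   `agreement_<plexus>.json`, `longitudinal_<plexus>_<method>.json` and
#'   `run_info.json`.
#' @param scaling a [scalingConfig()].
#' @param script a [scriptConfig()].
#' @param minQuality quality-index exclusion threshold (records must exceed
#'   it).
#' @param alpha level for correlation intervals.
#' @return Invisibly, `list(measurements, agreement, longitudinal,
#'   failures, excluded)`.
#' @export
runFullStudy <- function(imageDir, metaCsv, modelPath, outDir,
                         scaling = scalingConfig(), script = scriptConfig(),
                         minQuality = 15L, alpha = 0.05) {
  if (!dir.exists(imageDir)) stop("no scans: image directory not found")
  meta <- readMetadataCsv(metaCsv)
  if (!nrow(meta)) stop("no scans: empty metadata")
  flt <- filterQuality(meta, minQuality)
  kept <- flt$kept
  if (!nrow(kept)) stop("no scans passed the quality filter")
  model <- loadModel(modelPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(kept))) {
    row <- kept[i, ]
    res <- tryCatch({
      ang <- readAngiogram(file.path(imageDir, row$file),
                           metadata = metadataFromRow(row))
      regionS <- runScriptPipeline(ang, cfg = script)
      crop <- centerCrop(pixels(ang), script)
      cls <- classifyImage(crop, model)
      regionM <- extractFaz(cls$mask, center = script$wandSeed,
                            rescueRadius = script$seedRescueRadius)
      data.frame(
        subject_id = rep(row$subject_id, 2), eye = rep(row$eye, 2),
        visit = rep(row$visit, 2), plexus = rep(row$plexus, 2),
        method = c("script", "ml"),
        pixel_count = c(pixelCount(regionS), pixelCount(regionM)),
        area_mm2 = pixelsToAreaMm2(
          c(pixelCount(regionS), pixelCount(regionM)),
          row$axial_length_mm, scaling),
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[row$file]] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("no scans could be processed")
  measurements <- do.call(rbind, rows)
  writeMeasurements(measurements, file.path(outDir, "measurements.csv"))

  plexuses <- unique(measurements$plexus)
  agreement <- list()
  for (pl in plexuses) {
    rep_ <- tryCatch(agreementReport(measurements, pl, alpha = alpha),
                     error = function(e) list(plexus = pl,
                                              error = conditionMessage(e)))
    agreement[[pl]] <- rep_
    jsonlite::write_json(rep_, file.path(outDir,
                                         paste0("agreement_", pl, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  longitudinal <- list()
  for (pl in plexuses) {
    for (mth in c("script", "ml")) {
      key <- paste(pl, mth, sep = "_")
      rep_ <- tryCatch(longitudinalReport(measurements, pl, mth),
                       error = function(e) list(plexus = pl, method = mth,
                                                error = conditionMessage(e)))
      longitudinal[[key]] <- rep_
      jsonlite::write_json(rep_,
                           file.path(outDir,
                                     paste0("longitudinal_", key, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  info <- list(
    n_scans_total = nrow(meta), n_kept = nrow(kept),
    n_excluded_quality = nrow(flt$excluded),
    n_failed = length(failures), failures = failures,
    config_hash = objectHash(list(scaling = scaling, script = script,
                                  minQuality = minQuality, alpha = alpha)),
    model_hash = unname(tools::md5sum(modelPath)),
    model_seed = model@recipe$seed)
  jsonlite::write_json(info, file.path(outDir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(measurements = measurements, agreement = agreement,
                 longitudinal = longitudinal, failures = failures,
                 excluded = flt$excluded))
}
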