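# scaling: ocular magnification correction and pixel -> mm^2 conversion.

#' Scaling configuration
#'
#' The nominal image scale of the en-face scan (a `fieldMm` x `fieldMm`
#' field spanned by `nominalPx` pixels) and the reference axial length
#' assumed by the device. The default follows the 3 x 3 mm field sampled at
#' 510 pixels with a 23.95 mm reference axial length. `method` selects how
#' the magnification ratio is formed from the axial length: `"al_ratio"`
#' (the modified Bennett correction, AL / reference AL) or `"bennett_q"`
#' (the full Bennett q-ratio, (AL - 1.82) / (reference AL - 1.82), offered
#' for sensitivity analyses).
#'
#' @param fieldMm scan field width in mm.
#' @param nominalPx pixels spanning the field.
#' @param referenceAlMm reference axial length in mm.
#' @param method `"al_ratio"` (default) or `"bennett_q"`.
#' @return A validated config list of class `fazScalingConfig`.
#' @export
scalingConfig <- function(fieldMm = 3, nominalPx = 510L,
                          referenceAlMm = 23.95,
                          method = c("al_ratio", "bennett_q")) {
  method <- match.arg(method)
  if (fieldMm <= 0 || nominalPx <= 0 || referenceAlMm <= 0)
    stop("all scaling constants must be strictly positive")
  structure(list(fieldMm = as.numeric(fieldMm),
                 nominalPx = as.integer(nominalPx),
                 referenceAlMm = as.numeric(referenceAlMm),
                 method = method),
            class = "fazScalingConfig")
}

checkAl <- function(alMm) {
  if (!is.numeric(alMm) || anyNA(alMm) || any(alMm <= 15) || any(alMm >= 40))
    stop("axial length out of admissible range (15, 40) mm")
  as.numeric(alMm)
}

#' Ocular magnification factor
#'
#' The ratio of the measured axial length to the device's reference axial
#' length (modified Bennett correction), or the full Bennett q-ratio when
#' the config says so.
#'
#' @param alMm measured axial length in mm, in (15, 40).
#' @param cfg a [scalingConfig()].
#' @return The dimensionless magnification factor (1 at the reference AL).
#' @export
magnificationFactor <- function(alMm, cfg = scalingConfig()) {
  alMm <- checkAl(alMm)
  if (cfg$method == "al_ratio") alMm / cfg$referenceAlMm
  else (alMm - 1.82) / (cfg$referenceAlMm - 1.82)
}

#' Corrected image scale
#'
#' The nominal scale (field width over pixel count, mm per pixel) multiplied
#' by the magnification factor. Strictly positive and monotone increasing in
#' axial length.
#'
#' @inheritParams magnificationFactor
#' @return mm per pixel.
#' @export
correctedScale <- function(alMm, cfg = scalingConfig()) {
  (cfg$fieldMm / cfg$nominalPx) * magnificationFactor(alMm, cfg)
}

#' Convert a pixel count to retinal area in mm^2
#'
#' The corrected scale is squared and multiplied by the pixel count, so the
#' area scales exactly as (AL / reference AL)^2.
#'
#' @param pixelCount non-negative pixel count (vectorized).
#' @inheritParams magnificationFactor
#' @return Area in mm^2.
#' @export
pixelsToAreaMm2 <- function(pixelCount, alMm, cfg = scalingConfig()) {
  if (any(pixelCount < 0)) stop("pixel count must be non-negative")
  pixelCount * correctedScale(alMm, cfg)^2
}
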