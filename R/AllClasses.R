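#' @import methods
NULL

## Coordinate convention used throughout: 0-based row/column indices with
## pixel centers at integer coordinates. A pixel belongs to a circular ROI
## iff its center lies within the circle radius.

#' Scene description for the synthetic ACR-like phantom
#'
#' Parameters of a simulated axial slice through the homogeneous portion of
#' the ACR accreditation phantom: a uniform bright disc on dark background,
#' magnitude (Rician) noise, an optional N/2 ghost band and an optional
#' smooth intensity non-uniformity.
#'
#' @slot matrixSize pixels per image side.
#' @slot fovMm field of view in mm.
#' @slot phantomDiameterMm physical inside diameter of the phantom disc (mm).
#' @slot centerOffsetMm numeric(2), (row, col) offset of the phantom center
#'   from the image center, in mm.
#' @slot signalLevel noise-free in-phantom intensity.
#' @slot channelNoiseSd per-channel Gaussian noise SD (intensity units); the
#'   rendered magnitude image has Rician noise with this channel SD.
#' @slot ghostFraction fraction of \code{signalLevel} added as a ghost copy
#'   of the disc shifted by half the matrix along the phase-encode axis.
#' @slot ghostAxis phase-encode axis of the ghost, \code{"row"} or
#'   \code{"col"}.
#' @slot nonuniformityAmplitude peak-to-peak fractional modulation of the
#'   in-phantom signal across the disc.
#' @slot nonuniformityMode \code{"planar"} (linear gradient) or
#'   \code{"radial"} (parabolic dome).
#' @slot edgeSmoothing logical; linear intensity ramp over the one-pixel
#'   boundary shell instead of a hard edge.
#' @slot seed RNG seed for noise realizations.
#' @export
setClass("PhantomSceneSpec",
  representation(
    matrixSize = "integer",
    fovMm = "numeric",
    phantomDiameterMm = "numeric",
    centerOffsetMm = "numeric",
    signalLevel = "numeric",
    channelNoiseSd = "numeric",
    ghostFraction = "numeric",
    ghostAxis = "character",
    nonuniformityAmplitude = "numeric",
    nonuniformityMode = "character",
    edgeSmoothing = "logical",
    seed = "integer"
  )
)

setValidity("PhantomSceneSpec", function(object) {
  msg <- character()
  if (length(object@matrixSize) != 1L || object@matrixSize < 8L)
    msg <- c(msg, "matrixSize must be a single integer >= 8")
  if (object@fovMm <= 0) msg <- c(msg, "fovMm must be positive")
  if (length(object@centerOffsetMm) != 2L)
    msg <- c(msg, "centerOffsetMm must have length 2")
  if (object@phantomDiameterMm <= 0)
    msg <- c(msg, "phantomDiameterMm must be positive")
  if (object@phantomDiameterMm + 2 * max(abs(object@centerOffsetMm)) >=
      object@fovMm)
    msg <- c(msg, "phantom must lie fully inside the field of view")
  if (object@channelNoiseSd < 0) msg <- c(msg, "channelNoiseSd must be >= 0")
  if (object@ghostFraction < 0) msg <- c(msg, "ghostFraction must be >= 0")
  if (!object@ghostAxis %in% c("row", "col"))
    msg <- c(msg, "ghostAxis must be 'row' or 'col'")
  if (object@nonuniformityAmplitude < 0 || object@nonuniformityAmplitude >= 1)
    msg <- c(msg, "nonuniformityAmplitude must be in [0, 1)")
  if (!object@nonuniformityMode %in% c("planar", "radial"))
    msg <- c(msg, "nonuniformityMode must be 'planar' or 'radial'")
  if (length(msg)) msg else TRUE
})

#' One phantom slice image
#'
#' A single 2-D magnitude image of the phantom together with the acquisition
#' metadata the QC computations need. For synthetic slices the rendering
#' ground truth (true center, radius, signal) is carried in
#' \code{groundTruth}.
#'
#' @slot pixels numeric matrix of non-negative intensities (rows x cols).
#' @slot px,py pixel spacing in mm along columns / rows.
#' @slot sliceIndex ACR slice number, 1-11.
#' @slot seriesLabel "A" or "B".
#' @slot fieldStrengthT static field strength in Tesla.
#' @slot acquisitionTime acquisition time in seconds of day.
#' @slot sourceId provenance string.
#' @slot groundTruth list; for synthetic slices: centerRow, centerCol,
#'   radiusPx, signalLevel, channelNoiseSd. Empty for loaded data.
#' @export
setClass("AcquisitionSlice",
  representation(
    pixels = "matrix",
    px = "numeric",
    py = "numeric",
    sliceIndex = "integer",
    seriesLabel = "character",
    fieldStrengthT = "numeric",
    acquisitionTime = "numeric",
    sourceId = "character",
    groundTruth = "list"
  )
)

setValidity("AcquisitionSlice", function(object) {
  msg <- character()
  if (!all(dim(object@pixels) >= 1L)) msg <- c(msg, "pixels must be non-empty")
  if (object@px <= 0 || object@py <= 0)
    msg <- c(msg, "pixel spacing must be positive")
  if (any(object@pixels < 0)) msg <- c(msg, "intensities must be non-negative")
  if (object@sliceIndex < 1L || object@sliceIndex > 11L)
    msg <- c(msg, "sliceIndex must be in [1, 11]")
  if (!object@seriesLabel %in% c("A", "B"))
    msg <- c(msg, "seriesLabel must be 'A' or 'B'")
  if (length(msg)) msg else TRUE
})

#' Two sequential identical acquisitions
#'
#' Series A and B: the same 11-slice axial T1 sequence acquired twice with
#' identical settings a few minutes apart, enabling the across-acquisition
#' two-image SNR variant.
#'
#' @slot seriesA,seriesB lists of [AcquisitionSlice-class] objects.
#' @slot deltaTS seconds elapsed between the two acquisitions.
#' @export
setClass("StudyPair",
  representation(seriesA = "list", seriesB = "list", deltaTS = "numeric")
)

#' Detected phantom geometry
#'
#' Center, radius and in-phantom mask of the phantom disc as recovered by
#' [detectPhantom()]. All downstream ROI placement is expressed relative to
#' this geometry.
#'
#' @slot centerRow,centerCol subpixel center, 0-based pixel coordinates.
#' @slot r0Px phantom radius in pixels.
#' @slot r0Mm phantom radius in mm.
#' @slot mask logical matrix marking in-phantom pixels.
#' @slot quality fraction of mask pixels lying inside the fitted circle
#'   (plus a half-pixel tolerance); a segmentation diagnostic.
#' @export
setClass("PhantomGeometry",
  representation(
    centerRow = "numeric", centerCol = "numeric",
    r0Px = "numeric", r0Mm = "numeric",
    mask = "matrix", quality = "numeric"
  )
)

setValidity("PhantomGeometry", function(object) {
  msg <- character()
  if (object@r0Px <= 0) msg <- c(msg, "r0Px must be positive")
  d <- dim(object@mask)
  if (object@centerRow - object@r0Px < 0 ||
      object@centerRow + object@r0Px > d[1] - 1 ||
      object@centerCol - object@r0Px < 0 ||
      object@centerCol + object@r0Px > d[2] - 1)
    msg <- c(msg, "fitted circle must lie inside the image bounds")
  area <- sum(object@mask)
  if (abs(area - pi * object@r0Px^2) / (pi * object@r0Px^2) > 0.05)
    msg <- c(msg, "mask area inconsistent with fitted radius")
  if (length(msg)) msg else TRUE
})

#' Circular region of interest
#'
#' @slot centerRow,centerCol subpixel center (0-based).
#' @slot radiusPx radius in pixels.
#' @slot label one of "UFOV", "PIU_max", "PIU_min", "SNRU_center",
#'   "SNRU_U", "SNRU_D", "SNRU_L", "SNRU_R".
#' @export
setClass("CircularROI",
  representation(
    centerRow = "numeric", centerCol = "numeric",
    radiusPx = "numeric", label = "character"
  )
)

setValidity("CircularROI", function(object) {
  if (object@radiusPx <= 0) "radiusPx must be positive" else TRUE
})

#' Rectangular background bar ROI
#'
#' One of the four bar-shaped background ROIs placed up/down/left/right of
#' the phantom. \code{widthW} is the short dimension (towards/away from the
#' phantom), \code{heightH} the long one; for sides L/R the short dimension
#' runs along columns, for U/D along rows.
#'
#' @slot topRow,leftCol integer upper-left corner (0-based).
#' @slot widthW short dimension in pixels.
#' @slot heightH long dimension in pixels.
#' @slot side "U", "D", "L" or "R".
#' @export
setClass("RectROI",
  representation(
    topRow = "integer", leftCol = "integer",
    widthW = "integer", heightH = "integer", side = "character"
  )
)

setValidity("RectROI", function(object) {
  msg <- character()
  if (object@widthW < 1L || object@heightH < 1L)
    msg <- c(msg, "bar dimensions must be >= 1 pixel")
  if (!object@side %in% c("U", "D", "L", "R"))
    msg <- c(msg, "side must be one of U, D, L, R")
  if (length(msg)) msg else TRUE
})

#' Randomized ROI-placement configuration
#'
#' Standard deviations of the zero-mean normal perturbations applied to the
#' background bars to emulate manual ROI drawing: bar width, bar distance
#' from the phantom, and corner displacement along the long and short bar
#' dimensions.
#'
#' @slot nRuns number of randomized layouts.
#' @slot sdW SD of the width perturbation (pixels).
#' @slot sdGap SD of the phantom-distance perturbation (pixels).
#' @slot sdCornerLong SD of corner displacement along the long dimension.
#' @slot sdCornerShort SD of corner displacement along the short dimension.
#' @slot seed RNG seed.
#' @export
setClass("RandomizationConfig",
  representation(
    nRuns = "integer", sdW = "numeric", sdGap = "numeric",
    sdCornerLong = "numeric", sdCornerShort = "numeric", seed = "integer"
  )
)

setValidity("RandomizationConfig", function(object) {
  msg <- character()
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (any(c(object@sdW, object@sdGap, object@sdCornerLong,
            object@sdCornerShort) < 0))
    msg <- c(msg, "all perturbation SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Pixel statistics of one ROI
#'
#' @slot mean arithmetic mean intensity.
#' @slot sd population standard deviation (divide by n).
#' @slot nPixels number of member pixels.
#' @export
setClass("ROIStats",
  representation(mean = "numeric", sd = "numeric", nPixels = "integer")
)

setValidity("ROIStats", function(object) {
  msg <- character()
  if (object@nPixels < 1L) msg <- c(msg, "ROI must contain >= 1 pixel")
  if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One SNR value computed under a specific variant definition
#'
#' @slot tag variant identifier, e.g. "single_LR", "diff_76_avg".
#' @slot value the SNR estimate (dimensionless, >= 0).
#' @slot factorUsed the Rayleigh (single-image) or sqrt(2) (two-image)
#'   correction factor applied.
#' @slot components list of the contributing [ROIStats-class] / scalars.
#' @export
setClass("SNRVariant",
  representation(
    tag = "character", value = "numeric",
    factorUsed = "numeric", components = "list"
  )
)

setValidity("SNRVariant", function(object) {
  if (object@value < 0) "SNR value must be >= 0" else TRUE
})

#' Local-mean image used by the PIU computation
#'
#' The slice convolved with a binary disc mask of 1 cm^2 area, divided by
#' the mask pixel count, plus the mask parameters.
#'
#' @slot localMeanImage numeric matrix.
#' @slot maskRadiusPx mask radius in pixels.
#' @slot maskCount number of non-zero mask elements.
#' @export
setClass("PIUIntermediate",
  representation(
    localMeanImage = "matrix", maskRadiusPx = "integer", maskCount = "integer"
  )
)

#' Pass/fail limits of a QC protocol
#'
#' @slot name protocol name ("acr" or "greek").
#' @slot psgMax maximum acceptable PSG (percent).
#' @slot piuMin minimum acceptable PIU (percent).
#' @slot snrMinPerTesla SNR must be >= this times the field strength.
#' @slot ratioLow,ratioHigh acceptance interval for SNR/SNRU ratios.
#' @slot snruAchievable,snruMax SNRU reference levels (percent).
#' @export
setClass("ProtocolLimits",
  representation(
    name = "character", psgMax = "numeric", piuMin = "numeric",
    snrMinPerTesla = "numeric", ratioLow = "numeric", ratioHigh = "numeric",
    snruAchievable = "numeric", snruMax = "numeric"
  )
)

setValidity("ProtocolLimits", function(object) {
  msg <- character()
  if (!(object@ratioLow < 1 && 1 < object@ratioHigh))
    msg <- c(msg, "ratio interval must contain 1")
  if (any(c(object@psgMax, object@piuMin, object@snrMinPerTesla,
            object@snruAchievable, object@snruMax) <= 0))
    msg <- c(msg, "all limits must be positive")
  if (length(msg)) msg else TRUE
})

#' Full QC report for one study
#'
#' Aggregated metric values with their variant tags, randomized-PSG summary,
#' per-metric verdicts and provenance.
#'
#' @slot metrics named list of metric values and variants.
#' @slot verdicts data.frame with one row per checked limit.
#' @slot randomization list with the randomized-PSG summaries.
#' @slot provenance list: seed, protocol, factors, software version, inputs.
#' @slot notes character vector of notices (e.g. variants not computed).
#' @export
setClass("QCReport",
  representation(
    metrics = "list", verdicts = "data.frame",
    randomization = "list", provenance = "list", notes = "character"
  )
)
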