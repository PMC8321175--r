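#' Create a synthetic phantom scene description
#'
#' Defaults follow the standard ACR axial T1 acquisition: 256 x 256 matrix,
#' 250 mm field of view, 190 mm inside phantom diameter.
#'
#' @param matrixSize pixels per image side.
#' @param fovMm field of view in mm.
#' @param phantomDiameterMm phantom inside diameter in mm.
#' @param centerOffsetMm numeric(2): (row, col) phantom center offset in mm.
#' @param signalLevel noise-free in-phantom intensity.
#' @param channelNoiseSd per-channel Gaussian noise SD.
#' @param ghostFraction ghost amplitude as a fraction of \code{signalLevel}.
#' @param ghostAxis phase-encode axis of the ghost ("row" or "col").
#' @param nonuniformityAmplitude peak-to-peak fractional signal modulation.
#' @param nonuniformityMode "planar" or "radial".
#' @param edgeSmoothing smooth the disc edge over one pixel.
#' @param seed RNG seed.
#' @return a [PhantomSceneSpec-class] object.
#' @examples
#' spec <- phantomSceneSpec(signalLevel = 1000, channelNoiseSd = 10)
#' sl <- renderSlice(spec)
#' @export
phantomSceneSpec <- function(matrixSize = 256L, fovMm = 250,
                             phantomDiameterMm = 190,
                             centerOffsetMm = c(0, 0),
                             signalLevel = 1000, channelNoiseSd = 0,
                             ghostFraction = 0, ghostAxis = "row",
                             nonuniformityAmplitude = 0,
                             nonuniformityMode = "planar",
                             edgeSmoothing = FALSE, seed = 1L) {
  new("PhantomSceneSpec",
      matrixSize = as.integer(matrixSize), fovMm = fovMm,
      phantomDiameterMm = phantomDiameterMm,
      centerOffsetMm = as.numeric(centerOffsetMm),
      signalLevel = signalLevel, channelNoiseSd = channelNoiseSd,
      ghostFraction = ghostFraction, ghostAxis = ghostAxis,
      nonuniformityAmplitude = nonuniformityAmplitude,
      nonuniformityMode = nonuniformityMode,
      edgeSmoothing = edgeSmoothing, seed = as.integer(seed))
}

# Noise-free truth image plus the exact rendering geometry.
renderTruth <- function(spec) {
  n <- spec@matrixSize
  px <- spec@fovMm / n
  cr <- (n - 1) / 2 + spec@centerOffsetMm[1] / px
  cc <- (n - 1) / 2 + spec@centerOffsetMm[2] / px
  r0 <- spec@phantomDiameterMm / 2 / px

  row <- matrix(0:(n - 1), n, n)
  col <- matrix(0:(n - 1), n, n, byrow = TRUE)
  d <- sqrt((row - cr)^2 + (col - cc)^2)
  inside <- if (spec@edgeSmoothing) {
    pmin(pmax(r0 + 0.5 - d, 0), 1)  # linear ramp across the boundary shell
  } else {
    (d <= r0) * 1
  }

  mod <- 1
  a <- spec@nonuniformityAmplitude
  if (a > 0) {
    mod <- if (spec@nonuniformityMode == "planar") {
      1 + (a / 2) * (col - cc) / r0
    } else {
      1 + a / 2 - a * (d / r0)^2
    }
  }
  truth <- spec@signalLevel * inside * mod

  if (spec@ghostFraction > 0) {
    # Classic N/2 ghost: the disc support replicated half the matrix away
    # along the phase-encode axis (with wrap-around), at a fraction of the
    # in-phantom signal.
    shift <- n %/% 2
    support <- (d <= r0) * 1
    ghost <- if (spec@ghostAxis == "row") {
      support[((seq_len(n) - 1 - shift) %% n) + 1, , drop = FALSE]
    } else {
      support[, ((seq_len(n) - 1 - shift) %% n) + 1, drop = FALSE]
    }
    truth <- truth + spec@ghostFraction * spec@signalLevel * ghost
  }

  list(truth = truth, centerRow = cr, centerCol = cc, radiusPx = r0, px = px)
}

# Magnitude (Rician) noise: sqrt((truth + n1)^2 + n2^2) with two
# independent Gaussian channels; zero-signal background becomes Rayleigh.
applyMagnitudeNoise <- function(truth, sd) {
  if (sd == 0) return(truth)
  n <- length(truth)
  n1 <- stats::rnorm(n, 0, sd)
  n2 <- stats::rnorm(n, 0, sd)
  matrix(sqrt((truth + n1)^2 + n2^2), nrow(truth), ncol(truth))
}

#' Render one synthetic phantom slice
#'
#' Renders the noise-free truth (uniform disc, optional non-uniformity and
#' ghost band) and applies magnitude noise from two independent Gaussian
#' channels, so background noise follows the Rayleigh distribution as in
#' real magnitude-reconstructed MR images.
#'
#' @param spec a [PhantomSceneSpec-class].
#' @param sliceIndex ACR slice number to stamp on the result.
#' @param seriesLabel "A" or "B".
#' @param signalScale multiplier on the truth signal (used for drift).
#' @param seed RNG seed override; defaults to \code{spec@seed}.
#' @return an [AcquisitionSlice-class] whose \code{groundTruth} records the
#'   exact center, radius (pixels), signal level and channel noise SD.
#' @export
renderSlice <- function(spec, sliceIndex = 7L, seriesLabel = "A",
                        signalScale = 1, seed = NULL) {
  validObject(spec)
  rt <- renderTruth(spec)
  truth <- rt$truth * signalScale
  useSeed <- if (is.null(seed)) spec@seed else as.integer(seed)
  pix <- withSeed(useSeed, applyMagnitudeNoise(truth, spec@channelNoiseSd))
  new("AcquisitionSlice",
      pixels = pix, px = rt$px, py = rt$px,
      sliceIndex = as.integer(sliceIndex), seriesLabel = seriesLabel,
      fieldStrengthT = 1.5, acquisitionTime = 0,
      sourceId = sprintf("synthetic seed=%d slice=%d", useSeed,
                         as.integer(sliceIndex)),
      groundTruth = list(centerRow = rt$centerRow, centerCol = rt$centerCol,
                         radiusPx = rt$radiusPx,
                         signalLevel = spec@signalLevel * signalScale,
                         channelNoiseSd = spec@channelNoiseSd))
}

#' Render a series of synthetic slices
#'
#' All slices share the geometry of \code{spec}; each gets an independent
#' noise realization from a seed derived deterministically from
#' \code{spec@seed}. A per-slice fractional signal drift can be applied to
#' emulate scanner instability between slices or acquisitions.
#'
#' @param spec a [PhantomSceneSpec-class].
#' @param nSlices number of slices (>= 1).
#' @param sliceGapDrift fractional signal change per slice step: slice i is
#'   scaled by \code{1 + (i - 1) * sliceGapDrift}.
#' @param sliceIndices ACR slice numbers; default 7, 6, 5, ...
#' @param seriesLabel "A" or "B".
#' @param acquisitionTime seconds of day stamped on all slices.
#' @return list of [AcquisitionSlice-class].
#' @export
renderSeries <- function(spec, nSlices, sliceGapDrift = 0,
                         sliceIndices = NULL, seriesLabel = "A",
                         acquisitionTime = 0) {
  validObject(spec)
  nSlices <- as.integer(nSlices)
  if (nSlices < 1L) stopQc("synth", "nSlices must be >= 1")
  if (is.null(sliceIndices)) {
    sliceIndices <- 7L - (seq_len(nSlices) - 1L)
    sliceIndices <- pmax(sliceIndices, 1L)
  }
  lapply(seq_len(nSlices), function(i) {
    sl <- renderSlice(spec, sliceIndex = sliceIndices[i],
                      seriesLabel = seriesLabel,
                      signalScale = 1 + (i - 1) * sliceGapDrift,
                      seed = deriveSeed(spec@seed,
                                        i + 100L * (seriesLabel == "B")))
    sl@acquisitionTime <- acquisitionTime
    sl
  })
}
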