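#' Mean / SD / pixel count of one ROI
#'
#' The SD is the population SD (divide by n), the convention used for all
#' pixel-level statistics in the pipeline.
#'
#' @param image numeric matrix.
#' @param roi a [CircularROI-class] or [RectROI-class].
#' @return an [ROIStats-class].
#' @export
roiStats <- function(image, roi) {
  v <- roiPixelValues(image, roi)
  if (length(v) == 0L) stopQc("metrics", "ROI contains no pixels")
  new("ROIStats", mean = mean(v), sd = popSd(v), nPixels = length(v))
}

#' Percent signal ghosting
#'
#' \deqn{PSG = 100 \left| \frac{(\bar S_R + \bar S_L) - (\bar S_U + \bar S_D)}
#' {2 \bar S} \right|}
#' where \eqn{\bar S} is the mean over the UFOV circle and the four terms
#' are the mean intensities of the background bars. Pass limits: 2.5 percent
#' (ACR) and 1 percent (AAPM / Greek protocol).
#'
#' @param sPhantom [ROIStats-class] of the UFOV circle.
#' @param sU,sD,sL,sR [ROIStats-class] of the four bars.
#' @return list: value (percent), passAcr, passGreek.
#' @export
computePsg <- function(sPhantom, sU, sD, sL, sR) {
  if (roiMean(sPhantom) <= 0)
    stopQc("metrics", "phantom mean must be positive for PSG")
  v <- 100 * abs(((roiMean(sR) + roiMean(sL)) -
                  (roiMean(sU) + roiMean(sD))) / (2 * roiMean(sPhantom)))
  list(value = v, passAcr = v <= 2.5, passGreek = v <= 1.0)
}

#' Randomized PSG distribution
#'
#' Recomputes PSG for each randomized background-bar layout while keeping
#' the UFOV fixed, emulating the spread induced by manual ROI placement.
#'
#' @param image numeric matrix (slice #7).
#' @param geometry a [PhantomGeometry-class].
#' @param cfg a [RandomizationConfig-class].
#' @param px,py pixel spacing in mm.
#' @param ufovFraction UFOV radius fraction.
#' @return numeric vector of \code{cfg@nRuns} PSG values (percent).
#' @export
randomizedPsg <- function(image, geometry, cfg, px, py, ufovFraction = 0.8) {
  base <- placeBackgroundBars(geometry, dim(image), px, py)
  layouts <- randomizeBars(base, geometry, cfg, dim(image), px, py)
  sP <- roiStats(image, placeUfov(geometry, ufovFraction))
  vapply(layouts, function(lay) {
    computePsg(sP,
               roiStats(image, lay$U), roiStats(image, lay$D),
               roiStats(image, lay$L), roiStats(image, lay$R))$value
  }, numeric(1))
}

#' Local-mean image for the PIU computation
#'
#' Convolves the slice with a binary disc mask whose area is 1 cm^2
#' (radius \code{ceiling(10 / (px * sqrt(pi)))} pixels) and divides by the
#' mask pixel count, yielding at every pixel the mean intensity of the
#' 1 cm^2 neighborhood.
#'
#' @param image numeric matrix.
#' @param px,py pixel spacing in mm (py defaults to px).
#' @return a [PIUIntermediate-class].
#' @export
localMean <- function(image, px, py = px) {
  if (px <= 0 || py <= 0) stopQc("metrics", "pixel spacing must be positive")
  r <- as.integer(ceiling(10 / (px * sqrt(pi))))
  sz <- 2L * r + 1L
  off <- matrix(-r:r, sz, sz)
  mask <- (off^2 + t(off)^2) <= r^2
  nm <- sum(mask)
  i1 <- EBImage::filter2(image, mask / nm, boundary = 0)
  new("PIUIntermediate",
      localMeanImage = matrix(as.numeric(i1), nrow(image), ncol(image)),
      maskRadiusPx = r, maskCount = as.integer(nm))
}

#' Percentage image uniformity
#'
#' Finds the 1 cm^2 neighborhoods with the highest and lowest local mean
#' whose full disc mask lies inside the UFOV, then
#' \deqn{PIU = 100 \left[ 1 - \frac{\bar S_{max} - \bar S_{min}}
#' {\bar S_{max} + \bar S_{min}} \right].}
#' Pass limits: 87.5 percent (ACR, < 3 T) and 90 percent (AAPM / Greek).
#' Extremum ties are broken by first occurrence in row-major scan order.
#'
#' @param image numeric matrix (slice #7).
#' @param geometry a [PhantomGeometry-class].
#' @param px,py pixel spacing in mm.
#' @param ufovFraction UFOV radius fraction (default 0.8).
#' @return list: value (percent), sMax, sMin, maxRoi, minRoi
#'   ([CircularROI-class] at the extrema), intermediate
#'   ([PIUIntermediate-class]), passAcr, passGreek.
#' @export
computePiu <- function(image, geometry, px, py = px, ufovFraction = 0.8) {
  lm <- localMean(image, px, py)
  r <- lm@maskRadiusPx
  searchR <- ufovFraction * geometry@r0Px - r
  if (searchR <= 0)
    stopQc("metrics", "UFOV too small to contain the 1 cm^2 mask")
  d <- dim(image)
  rows <- matrix(0:(d[1] - 1), d[1], d[2])
  cols <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  ok <- (rows - geometry@centerRow)^2 + (cols - geometry@centerCol)^2 <=
    searchR^2

  # row-major candidate order for deterministic tie-breaking
  ordRM <- order(rows[ok], cols[ok])
  vals <- lm@localMeanImage[ok][ordRM]
  rr <- rows[ok][ordRM]; cc <- cols[ok][ordRM]
  iMax <- which.max(vals); iMin <- which.min(vals)
  sMax <- vals[iMax]; sMin <- vals[iMin]
  piu <- 100 * (1 - (sMax - sMin) / (sMax + sMin))
  list(value = piu, sMax = sMax, sMin = sMin,
       maxRoi = new("CircularROI", centerRow = rr[iMax], centerCol = cc[iMax],
                    radiusPx = as.numeric(r), label = "PIU_max"),
       minRoi = new("CircularROI", centerRow = rr[iMin], centerCol = cc[iMin],
                    radiusPx = as.numeric(r), label = "PIU_min"),
       intermediate = lm, passAcr = piu >= 87.5, passGreek = piu >= 90)
}

#' Single-image SNR
#'
#' \deqn{SNR = f \cdot \bar S / \bar\sigma_{bkg}} with \eqn{\bar\sigma_{bkg}}
#' the mean SD of the selected background bar(s) and \eqn{f} the Rayleigh
#' correction factor for the magnitude background (default 0.655).
#'
#' @param sPhantom [ROIStats-class] of the UFOV.
#' @param bars list of one or two [ROIStats-class] background bars.
#' @param factor Rayleigh correction factor.
#' @param tag variant tag, e.g. "single_LR".
#' @return an [SNRVariant-class].
#' @export
computeSnrSingle <- function(sPhantom, bars, factor = 0.655,
                             tag = "single") {
  if (!is.list(bars)) bars <- list(bars)
  sds <- vapply(bars, roiSd, numeric(1))
  if (any(sds <= 0))
    stopQc("metrics", "zero background SD; cannot form SNR (division by zero)")
  new("SNRVariant", tag = tag,
      value = factor * roiMean(sPhantom) / mean(sds),
      factorUsed = factor,
      components = list(signal = roiMean(sPhantom), barSds = sds))
}

#' Two-image (subtraction) SNR
#'
#' \deqn{SNR = f \cdot \bar S / \sigma_{diff}} with \eqn{\sigma_{diff}} the
#' SD of the difference image inside the UFOV and \eqn{f \approx \sqrt 2}
#' (default 1.41). The numerator is the UFOV mean of the first image, the
#' second, or their average. Applies both to slices #7/#6 of one
#' acquisition and to slice #7 of series A/B.
#'
#' @param stats1,stats2 [ROIStats-class] of the UFOV on the two images.
#' @param diffSd SD of the difference image over the same UFOV.
#' @param numeratorMode "first", "second" or "average".
#' @param factor subtraction noise correction (default 1.41).
#' @param tag variant tag.
#' @return an [SNRVariant-class].
#' @export
computeSnrDiff <- function(stats1, stats2, diffSd,
                           numeratorMode = c("first", "second", "average"),
                           factor = 1.41, tag = "diff") {
  numeratorMode <- match.arg(numeratorMode)
  if (diffSd <= 0)
    stopQc("metrics", "difference image has zero SD (identical images?)")
  num <- switch(numeratorMode,
                first = roiMean(stats1), second = roiMean(stats2),
                average = (roiMean(stats1) + roiMean(stats2)) / 2)
  new("SNRVariant", tag = tag, value = factor * num / diffSd,
      factorUsed = factor,
      components = list(s1 = roiMean(stats1), s2 = roiMean(stats2),
                        sdDiff = diffSd, numeratorMode = numeratorMode))
}

#' SD of a difference image over the UFOV
#'
#' Computed in signed arithmetic; population SD.
#'
#' @param image1,image2 numeric matrices of equal dim.
#' @param ufov the UFOV [CircularROI-class].
#' @return numeric SD.
#' @export
ufovDiffSd <- function(image1, image2, ufov) {
  popSd(roiPixelValues(image1 - image2, ufov))
}

#' Ratio of two SNR variants
#'
#' @param v1,v2 [SNRVariant-class] objects (or numeric values).
#' @param ratioLow,ratioHigh acceptance interval (default 0.9 - 1.1).
#' @return list: ratio, pass.
#' @export
snrRatio <- function(v1, v2, ratioLow = 0.9, ratioHigh = 1.1) {
  x1 <- if (is(v1, "SNRVariant")) variantValue(v1) else v1
  x2 <- if (is(v2, "SNRVariant")) variantValue(v2) else v2
  if (x2 <= 0) stopQc("metrics", "zero denominator SNR in ratio")
  r <- x1 / x2
  list(ratio = r, pass = r >= ratioLow && r <= ratioHigh)
}

#' SNR uniformity across the five circles
#'
#' Each circle's SNR is formed either from the background-bar SDs
#' (single-image variant: \eqn{SNR_i = 2 f \bar S_i / (\sigma_L + \sigma_R)})
#' or from the per-circle SD of the subtraction image (two-image variant:
#' \eqn{SNR_i = f \bar S_i / \sigma_{i,D}}); then
#' \deqn{SNRU = 100 \cdot sd(SNR_1..SNR_5) / mean(SNR_1..SNR_5)}
#' using the sample SD over the five values. Reference levels: 5 percent
#' (achievable) and 10 percent (maximum acceptable).
#'
#' @param roiMeans numeric(5): mean intensities of the five circles.
#' @param barSds numeric(2) (sigma_L, sigma_R) for the single-image variant.
#' @param diffSds numeric(5) per-circle subtraction-image SDs for the
#'   two-image variant (exactly one of barSds / diffSds must be given).
#' @param factor correction factor (0.655 single-image, 1.41 two-image).
#' @return list: value (percent), snr (the five SNR values).
#' @export
computeSnru <- function(roiMeans, barSds = NULL, diffSds = NULL,
                        factor = if (is.null(diffSds)) 0.655 else 1.41) {
  if (length(roiMeans) != 5L)
    stopQc("metrics", "SNRU needs exactly five ROI means")
  if (is.null(barSds) == is.null(diffSds))
    stopQc("metrics", "give exactly one of barSds or diffSds")
  snr <- if (!is.null(barSds)) {
    if (sum(barSds) <= 0) stopQc("metrics", "zero background SD")
    2 * factor * roiMeans / (barSds[1] + barSds[2])
  } else {
    if (any(diffSds <= 0)) stopQc("metrics", "zero subtraction-image SD")
    factor * roiMeans / diffSds
  }
  m <- mean(snr)
  if (m <= 0) stopQc("metrics", "zero mean SNR")
  list(value = 100 * stats::sd(snr) / m, snr = snr)
}
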