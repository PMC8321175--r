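#' Detect the phantom disc in a slice
#'
#' Segments the bright quasi-circular phantom against the dark background:
#' Otsu threshold on normalized intensity, largest connected component,
#' hole filling, intensity-weighted centroid as the (subpixel) center, and
#' radius from the component area (\eqn{r_0 = \sqrt{area/\pi}}). The
#' procedure is parameter-free and invariant to global intensity scaling.
#'
#' @param slice an [AcquisitionSlice-class].
#' @param minPhantomFraction minimum fraction of the image area the phantom
#'   component must cover (default 0.05).
#' @return a [PhantomGeometry-class].
#' @export
detectPhantom <- function(slice, minPhantomFraction = 0.05) {
  x <- slice@pixels
  rng <- range(x)
  if (rng[2] <= rng[1])
    stopQc("detection", "image is constant; no phantom found")
  x01 <- (x - rng[1]) / (rng[2] - rng[1])

  th <- EBImage::otsu(x01)
  bw <- x01 > th
  lab <- EBImage::bwlabel(bw)
  if (max(lab) < 1)
    stopQc("detection", "no bright connected region found")
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  if (sizes[comp] < minPhantomFraction * length(x))
    stopQc("detection", "largest bright region covers only ",
           sprintf("%.1f%%", 100 * sizes[comp] / length(x)),
           " of the image (< ", 100 * minPhantomFraction, "%)")
  mask <- EBImage::fillHull(lab == comp) > 0
  mask <- matrix(as.logical(mask), nrow(x), ncol(x))

  idx <- which(mask, arr.ind = TRUE)
  w <- x[mask]
  cr <- sum((idx[, 1] - 1) * w) / sum(w)
  cc <- sum((idx[, 2] - 1) * w) / sum(w)
  area <- nrow(idx)
  r0 <- sqrt(area / pi)

  d <- dim(x)
  if (cr - r0 < 0 || cr + r0 > d[1] - 1 || cc - r0 < 0 || cc + r0 > d[2] - 1)
    stopQc("detection",
           "phantom circle touches the image border; background ROIs ",
           "cannot be placed")

  dist <- sqrt((idx[, 1] - 1 - cr)^2 + (idx[, 2] - 1 - cc)^2)
  quality <- mean(dist <= r0 + 0.5)

  new("PhantomGeometry",
      centerRow = cr, centerCol = cc, r0Px = r0, r0Mm = r0 * slice@px,
      mask = mask, quality = quality)
}

#' Recovered phantom diameter in mm
#'
#' Consistency check of the detected geometry against the known 190 mm
#' inside diameter of the ACR phantom.
#'
#' @param geometry a [PhantomGeometry-class].
#' @param px pixel spacing in mm.
#' @param expectedDiameterMm expected diameter (default 190 mm).
#' @param toleranceMm warn when outside expected +/- tolerance (default 10).
#' @return diameter in mm.
#' @export
phantomDiameterMm <- function(geometry, px, expectedDiameterMm = 190,
                              toleranceMm = 10) {
  d <- 2 * geometry@r0Px * px
  if (abs(d - expectedDiameterMm) > toleranceMm)
    warning(sprintf(
      "detected phantom diameter %.1f mm outside %.0f +/- %.0f mm",
      d, expectedDiameterMm, toleranceMm))
  d
}
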