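# Pixel extents of a bar: widthW runs along the short axis (towards the
# phantom), heightH along the long one. 0-based inclusive ranges.
rectExtent <- function(roi) {
  if (roi@side %in% c("L", "R")) {
    list(rows = roi@topRow:(roi@topRow + roi@heightH - 1L),
         cols = roi@leftCol:(roi@leftCol + roi@widthW - 1L))
  } else {
    list(rows = roi@topRow:(roi@topRow + roi@widthW - 1L),
         cols = roi@leftCol:(roi@leftCol + roi@heightH - 1L))
  }
}

#' Pixel values covered by an ROI
#'
#' Membership rule: a pixel belongs to a circular ROI iff its center lies
#' within the radius; rectangular ROIs cover whole pixels.
#'
#' @param image numeric matrix.
#' @param roi a [CircularROI-class] or [RectROI-class].
#' @return numeric vector of member pixel values.
#' @export
roiPixelValues <- function(image, roi) {
  d <- dim(image)
  if (is(roi, "CircularROI")) {
    r <- roi@radiusPx
    rows <- max(0, floor(roi@centerRow - r)):min(d[1] - 1, ceiling(roi@centerRow + r))
    cols <- max(0, floor(roi@centerCol - r)):min(d[2] - 1, ceiling(roi@centerCol + r))
    if (roi@centerRow - r < -0.5 || roi@centerRow + r > d[1] - 0.5 ||
        roi@centerCol - r < -0.5 || roi@centerCol + r > d[2] - 0.5)
      stopQc("roi", "circular ROI extends outside the image")
    sub <- image[rows + 1L, cols + 1L, drop = FALSE]
    rg <- matrix(rows, length(rows), length(cols))
    cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    inside <- (rg - roi@centerRow)^2 + (cg - roi@centerCol)^2 <= r^2
    sub[inside]
  } else if (is(roi, "RectROI")) {
    e <- rectExtent(roi)
    if (min(e$rows) < 0 || max(e$rows) > d[1] - 1 ||
        min(e$cols) < 0 || max(e$cols) > d[2] - 1)
      stopQc("roi", "rectangular ROI extends outside the image")
    as.vector(image[e$rows + 1L, e$cols + 1L])
  } else stopQc("roi", "unsupported ROI class ", class(roi))
}

#' Place the UFOV circle
#'
#' The useful field of view: a circle concentric with the phantom at 0.8
#' times the phantom radius, i.e. 64 percent of the phantom area.
#'
#' @param geometry a [PhantomGeometry-class].
#' @param ufovFraction radius fraction (default 0.8).
#' @return a [CircularROI-class] labelled "UFOV".
#' @export
placeUfov <- function(geometry, ufovFraction = 0.8) {
  new("CircularROI",
      centerRow = geometry@centerRow, centerCol = geometry@centerCol,
      radiusPx = ufovFraction * geometry@r0Px, label = "UFOV")
}

# Long bar dimension sized so the bar area is 10 cm^2 = 1000 mm^2.
barLongDim <- function(w, px, py) max(1L, as.integer(round(1000 / (w * px * py))))

# Center an extent of length len on axis position c0, clip into [0, n-1].
centerAndClip <- function(c0, len, n) {
  len <- as.integer(min(len, n))
  start <- as.integer(round(c0 - (len - 1) / 2))
  start <- as.integer(max(0L, min(start, as.integer(n) - len)))
  list(start = start, len = len)
}

#' Place the four background bars
#'
#' For each side (up, down, left, right) the bar fills the strip between
#' 0.1 R0 away from the phantom edge and 0.1 R0 away from the image
#' border; its short dimension w is the full strip width and its long
#' dimension is \code{round(1000 / (w px py))} pixels so the bar area is
#' 10 cm^2. Bars are centered on the phantom's row/column axis; a long
#' dimension exceeding the image is clipped with a warning.
#'
#' @param geometry a [PhantomGeometry-class].
#' @param imageShape integer(2): image dim (rows, cols).
#' @param px,py pixel spacing in mm.
#' @param marginFraction gap on both sides of the strip as a fraction of
#'   R0 (default 0.1).
#' @return named list of four [RectROI-class] objects (U, D, L, R).
#' @export
placeBackgroundBars <- function(geometry, imageShape, px, py,
                                marginFraction = 0.1) {
  nr <- imageShape[1]; nc <- imageShape[2]
  cr <- geometry@centerRow; cc <- geometry@centerCol
  r0 <- geometry@r0Px
  m <- marginFraction * r0

  gaps <- c(U = cr - r0, D = (nr - 1) - cr - r0,
            L = cc - r0, R = (nc - 1) - cc - r0)
  if (any(gaps < 2 * m + 2))
    stopQc("roi", "insufficient background margin around the phantom (",
           sprintf("min gap %.1f px, need %.1f", min(gaps), 2 * m + 2), ")")

  mk <- function(side) {
    if (side == "L") { a <- ceiling(m); b <- floor(cc - r0 - m) }
    if (side == "R") { a <- ceiling(cc + r0 + m); b <- floor((nc - 1) - m) }
    if (side == "U") { a <- ceiling(m); b <- floor(cr - r0 - m) }
    if (side == "D") { a <- ceiling(cr + r0 + m); b <- floor((nr - 1) - m) }
    w <- as.integer(b - a + 1)
    if (w < 1L) stopQc("roi", "no room for background bar on side ", side)
    H <- barLongDim(w, px, py)
    if (side %in% c("L", "R")) {
      cl <- centerAndClip(cr, H, nr)
      if (cl$len < H) warning("bar ", side, " long dimension clipped to image")
      new("RectROI", topRow = cl$start, leftCol = as.integer(a),
          widthW = w, heightH = cl$len, side = side)
    } else {
      cl <- centerAndClip(cc, H, nc)
      if (cl$len < H) warning("bar ", side, " long dimension clipped to image")
      new("RectROI", topRow = as.integer(a), leftCol = cl$start,
          widthW = w, heightH = cl$len, side = side)
    }
  }
  list(U = mk("U"), D = mk("D"), L = mk("L"), R = mk("R"))
}

#' Randomization configuration constructor
#'
#' Defaults reproduce the emulation of manual ROI drawing: unit-SD
#' perturbations of bar width and phantom distance, and corner jitter with
#' SD 1 pixel along the long bar dimension and 3 pixels along the short
#' one.
#'
#' @param nRuns number of randomized layouts (default 500).
#' @param sdW,sdGap,sdCornerLong,sdCornerShort perturbation SDs in pixels.
#' @param seed RNG seed.
#' @return a [RandomizationConfig-class].
#' @export
randomizationConfig <- function(nRuns = 500L, sdW = 1, sdGap = 1,
                                sdCornerLong = 1, sdCornerShort = 3,
                                seed = 1L) {
  new("RandomizationConfig", nRuns = as.integer(nRuns), sdW = sdW,
      sdGap = sdGap, sdCornerLong = sdCornerLong,
      sdCornerShort = sdCornerShort, seed = as.integer(seed))
}

# TRUE when the bar lies inside the image and clear of the phantom circle.
barValid <- function(roi, geometry, imageShape) {
  e <- tryCatch(rectExtent(roi), error = function(e) NULL)
  if (is.null(e)) return(FALSE)
  if (min(e$rows) < 0 || max(e$rows) > imageShape[1] - 1 ||
      min(e$cols) < 0 || max(e$cols) > imageShape[2] - 1) return(FALSE)
  # nearest point of the rectangle to the phantom center
  nr <- min(max(geometry@centerRow, min(e$rows)), max(e$rows))
  nc <- min(max(geometry@centerCol, min(e$cols)), max(e$cols))
  sqrt((nr - geometry@centerRow)^2 + (nc - geometry@centerCol)^2) >
    geometry@r0Px
}

#' Generate randomized background-bar layouts
#'
#' Emulates manual placement: per run and per side the bar width, its
#' distance from the phantom, and its corner position are perturbed by
#' zero-mean normal deviates with the configured SDs; the long dimension is
#' recomputed from the perturbed width so every bar keeps a 10 cm^2 area.
#' Layouts that overlap the phantom or cross the image border are rejected
#' and resampled (bounded retries). Reproducible for a fixed seed.
#'
#' @param base named list (U, D, L, R) from [placeBackgroundBars()].
#' @param geometry a [PhantomGeometry-class].
#' @param cfg a [RandomizationConfig-class].
#' @param imageShape integer(2) image dim.
#' @param px,py pixel spacing in mm.
#' @return list of \code{nRuns} layouts, each a named list of four
#'   [RectROI-class] objects.
#' @export
randomizeBars <- function(base, geometry, cfg, imageShape, px, py) {
  validObject(cfg)
  maxRetry <- 200L
  attempts <- 0L
  rejected <- 0L
  cr <- geometry@centerRow; cc <- geometry@centerCol

  sampleSide <- function(side) {
    b <- base[[side]]
    # inner (phantom-facing) short-axis edge of the base bar
    innerEdge <- switch(side,
      L = b@leftCol + b@widthW - 1L, R = b@leftCol,
      U = b@topRow + b@widthW - 1L, D = b@topRow)
    for (try in seq_len(maxRetry)) {
      attempts <<- attempts + 1L
      w <- max(1L, as.integer(round(b@widthW + stats::rnorm(1, 0, cfg@sdW))))
      H <- barLongDim(w, px, py)
      edge <- innerEdge + stats::rnorm(1, 0, cfg@sdGap)
      dLong <- stats::rnorm(1, 0, cfg@sdCornerLong)
      dShort <- stats::rnorm(1, 0, cfg@sdCornerShort)
      roi <- if (side %in% c("L", "R")) {
        s <- if (side == "L") round(edge) - w + 1L else round(edge)
        new("RectROI",
            topRow = as.integer(round(cr - (H - 1) / 2 + dLong)),
            leftCol = as.integer(s + round(dShort)),
            widthW = w, heightH = H, side = side)
      } else {
        s <- if (side == "U") round(edge) - w + 1L else round(edge)
        new("RectROI",
            topRow = as.integer(s + round(dShort)),
            leftCol = as.integer(round(cc - (H - 1) / 2 + dLong)),
            widthW = w, heightH = H, side = side)
      }
      if (barValid(roi, geometry, imageShape)) return(roi)
      rejected <<- rejected + 1L
    }
    stopQc("roi", "could not place a valid randomized bar on side ", side,
           " after ", maxRetry, " attempts")
  }

  layouts <- withSeed(cfg@seed, {
    lapply(seq_len(cfg@nRuns), function(run) {
      sides <- lapply(c(U = "U", D = "D", L = "L", R = "R"), sampleSide)
      sides
    })
  })
  if (attempts > 0 && rejected / attempts > 0.99)
    stopQc("roi", "randomization rejection rate above 99%; check the ",
           "perturbation SDs against the available background margin")
  layouts
}

#' Place the five SNR-uniformity circles
#'
#' A circle of approximately 1 cm radius at the phantom center and four
#' identical circles above, below, left and right of it at a distance of
#' R0/2.
#'
#' @param geometry a [PhantomGeometry-class].
#' @param px pixel spacing in mm.
#' @param snruRadiusMm circle radius in mm (default 10).
#' @return named list of five [CircularROI-class]: center, U, D, L, R.
#' @export
placeSnruRois <- function(geometry, px, snruRadiusMm = 10) {
  r <- ceiling(snruRadiusMm / px)
  cr <- geometry@centerRow; cc <- geometry@centerCol
  h <- geometry@r0Px / 2
  mk <- function(dr, dc, lab)
    new("CircularROI", centerRow = cr + dr, centerCol = cc + dc,
        radiusPx = r, label = lab)
  list(center = mk(0, 0, "SNRU_center"),
       U = mk(-h, 0, "SNRU_U"), D = mk(h, 0, "SNRU_D"),
       L = mk(0, -h, "SNRU_L"), R = mk(0, h, "SNRU_R"))
}
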