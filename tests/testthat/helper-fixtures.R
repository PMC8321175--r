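# Fixtures built in code: ROI statistics, phantom geometries and standard
# synthetic scenes shared across test files.

mkStats <- function(mean, sd = 0, n = 10L) {
  new("ROIStats", mean = mean, sd = sd, nPixels = as.integer(n))
}

# Geometry with an exact pixel-center-rasterized disc mask.
mkGeometry <- function(n, centerRow, centerCol, r0, px = 1) {
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  mask <- (rows - centerRow)^2 + (cols - centerCol)^2 <= r0^2
  new("PhantomGeometry", centerRow = centerRow, centerCol = centerCol,
      r0Px = r0, r0Mm = r0 * px, mask = mask, quality = 1)
}

# Standard acquisition-protocol scene: 256 matrix, 250 mm FOV, 190 mm disc.
cleanScene <- function(...) {
  phantomSceneSpec(signalLevel = 1000, channelNoiseSd = 0, ...)
}

noisyScene <- function(noiseSd = 10, seed = 11L, ...) {
  phantomSceneSpec(signalLevel = 1000, channelNoiseSd = noiseSd,
                   seed = seed, ...)
}

# Brute-force local disc mean at integer center (r0-based 0-indexed), the
# independent oracle for the PIU extremum search.
bruteDiscMean <- function(image, cr, cc, r) {
  n <- nrow(image); m <- ncol(image)
  acc <- 0; cnt <- 0L
  for (dr in -r:r) for (dc in -r:r) {
    if (dr^2 + dc^2 <= r^2) {
      rr <- cr + dr; cc2 <- cc + dc
      v <- if (rr < 0 || rr >= n || cc2 < 0 || cc2 >= m) 0
           else image[rr + 1L, cc2 + 1L]
      acc <- acc + v; cnt <- cnt + 1L
    }
  }
  acc / cnt
}
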