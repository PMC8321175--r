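#' Load a DICOM series from a directory
#'
#' Reads every \code{.dcm} file, checks that all belong to one series,
#' applies RescaleSlope/Intercept, and returns slices ordered by
#' InstanceNumber. The ACR slice number is taken from the InstanceNumber
#' order, optionally shifted for exports that include extra localizer
#' images.
#'
#' @param path directory containing the DICOM files of one series.
#' @param seriesLabel label to stamp on the slices ("A" or "B").
#' @param indexOffset added to the InstanceNumber rank to obtain the ACR
#'   slice number (default 0: instance i is ACR slice i).
#' @return list of [AcquisitionSlice-class], sorted by InstanceNumber.
#' @export
loadSeries <- function(path, seriesLabel = "A", indexOffset = 0L) {
  files <- list.files(path, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L)
    stopQc("io", "no DICOM files found in ", path)
  parsed <- lapply(files, readDicomFile)

  uids <- unique(vapply(parsed, function(p) p$seriesUid %||% "", character(1)))
  if (length(uids) > 1L)
    stopQc("io", "directory mixes multiple series: ",
           paste(uids, collapse = ", "))

  inst <- vapply(parsed, function(p) p$instanceNumber, integer(1))
  if (anyNA(inst)) inst <- seq_along(parsed)  # fallback: file order
  parsed <- parsed[order(inst)]

  lapply(seq_along(parsed), function(i) {
    p <- parsed[[i]]
    if (is.null(p$pixelSpacing))
      stopQc("io", "PixelSpacing missing in ", p$sourceId,
             " (needed to size the background ROIs)")
    if (abs(p$pixelSpacing[1] - p$pixelSpacing[2]) > 1e-9)
      warning("anisotropic pixel spacing in ", p$sourceId)
    vals <- p$pixels * p$rescaleSlope + p$rescaleIntercept
    new("AcquisitionSlice",
        pixels = vals,
        px = p$pixelSpacing[2], py = p$pixelSpacing[1],
        sliceIndex = as.integer(i + indexOffset),
        seriesLabel = seriesLabel,
        fieldStrengthT = if (is.na(p$fieldStrengthT)) 1.5 else p$fieldStrengthT,
        acquisitionTime = if (is.na(p$acquisitionTime)) 0 else p$acquisitionTime,
        sourceId = p$sourceId,
        groundTruth = list())
  })
}

#' Pair two sequential acquisitions into a study
#'
#' @param a,b slice lists of series A and B (same geometry required).
#' @param maxPairDeltaS warn when the acquisitions are further apart than
#'   this many seconds (default 300 s = the 5-minute pairing window).
#' @return a [StudyPair-class].
#' @export
pairSeries <- function(a, b, maxPairDeltaS = 300) {
  da <- dim(a[[1]]@pixels); db <- dim(b[[1]]@pixels)
  if (!identical(da, db))
    stopQc("pairing", "matrix size mismatch: ", paste(da, collapse = "x"),
           " vs ", paste(db, collapse = "x"))
  if (abs(a[[1]]@px - b[[1]]@px) > 1e-9 || abs(a[[1]]@py - b[[1]]@py) > 1e-9)
    stopQc("pairing", "pixel spacing mismatch between series")
  dt <- abs(b[[1]]@acquisitionTime - a[[1]]@acquisitionTime)
  if (is.na(dt)) dt <- 0
  if (dt > maxPairDeltaS)
    warning(sprintf(
      "series acquired %.0f s apart (> %.0f s pairing window)",
      dt, maxPairDeltaS))
  new("StudyPair", seriesA = a, seriesB = b, deltaTS = dt)
}

#' Select the slice with a given ACR slice number
#'
#' @param series list of [AcquisitionSlice-class].
#' @param index ACR slice number wanted.
#' @return the matching slice.
#' @export
selectSlice <- function(series, index) {
  ix <- vapply(series, sliceIndex, integer(1))
  hit <- which(ix == as.integer(index))
  if (length(hit) != 1L)
    stopQc("io", "series does not contain exactly one slice #", index)
  series[[hit]]
}
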